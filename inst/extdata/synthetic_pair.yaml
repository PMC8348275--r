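# Synthetic two-conformer example (generated by synthetic_molecule, seeds 101/102);
# not a real molecule - used by examples, tests and the CLI demo.
conformers:
- name: chainA
  rotor:
    A: 0.2003512
    B: 0.0696291
    C: 0.0648879
    unit: cm-1
  bands:
  - label: b01
    nu_calc: 524.7547295
    tensor:
      xx: 1.5577656
      yy: 1.0926249
      zz: 0.6786399
      xy: 0.2556393
      xz: -0.1510679
      yz: 0.3252802
  - label: b02
    nu_calc: 610.0932162
    tensor:
      xx: 1.9926881
      yy: 2.2637108
      zz: 1.3538268
      xy: 0.2517713
      xz: -0.3162131
      yz: 0.2823067
  - label: b03
    nu_calc: 1218.0736741
    tensor:
      xx: 0.5293495
      yy: 0.4853898
      zz: 0.571126
      xy: -0.1212957
      xz: 0.1079978
      yz: 0.0616337
  - label: b04
    nu_calc: 1306.4628311
    tensor:
      xx: 1.4366297
      yy: 1.3943422
      zz: 2.9556644
      xy: 0.7442115
      xz: 0.9448954
      yz: 0.0007182
  energetics:
    degeneracy: 1
    family: A
    energies:
      E0: 0.0
  provenance: synthetic (seed 101)
- name: chainB
  rotor:
    A: 0.2904234
    B: 0.089182
    C: 0.0728652
    unit: cm-1
  bands:
  - label: b01
    nu_calc: 249.6026044
    tensor:
      xx: 0.6567715
      yy: 1.440229
      zz: -2.0970005
      xy: 0.8058898
      xz: 0.2056798
      yz: 0.4555678
  - label: b02
    nu_calc: 815.0709487
    tensor:
      xx: 1.0976824
      yy: 1.5345623
      zz: 1.0322655
      xy: 0.1223307
      xz: 0.2402432
      yz: -0.1103866
  - label: b03
    nu_calc: 1018.5791927
    tensor:
      xx: -0.2724632
      yy: 1.404563
      zz: -1.1320998
      xy: -0.0068115
      xz: 0.8370511
      yz: 1.1274552
  - label: b04
    nu_calc: 1432.2819041
    tensor:
      xx: 0.4540782
      yy: 1.024352
      zz: 1.0600395
      xy: -0.0248455
      xz: -0.012547
      yz: -0.4401718
  energetics:
    degeneracy: 2
    family: B
    energies:
      E0: 0.4
  provenance: synthetic (seed 102)
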
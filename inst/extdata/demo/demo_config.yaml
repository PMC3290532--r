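seed: 424242
species:
- name: species_A
  genome_size_bp: 300000
  n_clones: 300
  insert_mean: 250.0
  insert_sd: 40.0
  families:
  - name: satA
    category: tandem-satellite
    consensus: TCTCAGGAGCGATATTATGTCACTTAATACGTGACTGATCCGTCATTTCTTCAGACCTAAGTGGGTGGGGGATCTACCCAGGCACATACCTGTGAGGTAATTCAGATACGTACGACTAACGGCGACCGAGTCACTACCTGCGAGATTGGT
    copies: 30
    units_per_array: 4
    divergence: 0.02
  - name: lineB
    category: LINE
    consensus: TACTCGTTTGTGTTTCCTATCGTCCTCATCCTGAAAAGCCAGCATGCGCTCTGGAGTTAATATACCCAGATCGTAATTCTCATTCAGAACGGGATTTACTCGGACCGGACAGGACCATCCCGGCCAGTAGGGCCCCTACCTAAACTAATTCTGGGTCTTTTACTCTTTACCAAAGGAGAGCTGTATTCCACGCTAATCTCACAATTAGTAATCGGTTCTTCTGGAATCTCCTGTGAGAGTACGAGATCGCCGGGTTCCGGCGCTTACGGCGTTGGCGAAAGATTCGTATTTTACTTCTGGAGCCAGCGATTATCCGGATTCCGGTATCTCAGAACTTTCATCAACGCTGCCACAGAGGTTCACTCACTACTAGCGTGCACCGGTAGACGCATTGTGAGGGCACGGATCAGTGGATGGTCTCATGGGCGCGCCTTGCTGGGTCCTATGTCTTTAAAACCTACAGGGATTAGTATCACTCTATAGCAATGGTTAGTACTCAAGACCCAGGATACTCAAGAGGGATGCGATAGTTGAGATAACGGCGATTTCCACCTGAGCAGATCCTAAGCGTTCCTACATCGGGATCCATGGTCTATGGGGCACTTCTCAAGTGCTGCGTAGATTACCCCGTCGCAAAGACACGAGTGGGAAACTGGATGGGTTGGCAGTGGTCCCATTCATGACGTAATAAGCTCTCAAGTTAGCCGTAGCCAATCCTCCATAAGGTTAACGCAAGCGGTCCTCTTCCACTGGTGTAAGATACTATCATGTCGGCAGATGCGGGGAGTTTTTGAGAGTTG
    copies: 15
    divergence: 0.03
- name: species_B
  genome_size_bp: 300000
  n_clones: 300
  insert_mean: 250.0
  insert_sd: 40.0
  families:
  - name: satA
    category: tandem-satellite
    consensus: TCTCAGGAGCGATATTATGTCACTTAATACGTGACTGATCCGTCATTTCTTCAGACCTAAGTGGGTGGGGGATCTACCCAGGCACATACCTGTGAGGTAATTCAGATACGTACGACTAACGGCGACCGAGTCACTACCTGCGAGATTGGT
    copies: 8
    units_per_array: 4
    divergence: 0.02
  - name: lineB
    category: LINE
    consensus: TACTCGTTTGTGTTTCCTATCGTCCTCATCCTGAAAAGCCAGCATGCGCTCTGGAGTTAATATACCCAGATCGTAATTCTCATTCAGAACGGGATTTACTCGGACCGGACAGGACCATCCCGGCCAGTAGGGCCCCTACCTAAACTAATTCTGGGTCTTTTACTCTTTACCAAAGGAGAGCTGTATTCCACGCTAATCTCACAATTAGTAATCGGTTCTTCTGGAATCTCCTGTGAGAGTACGAGATCGCCGGGTTCCGGCGCTTACGGCGTTGGCGAAAGATTCGTATTTTACTTCTGGAGCCAGCGATTATCCGGATTCCGGTATCTCAGAACTTTCATCAACGCTGCCACAGAGGTTCACTCACTACTAGCGTGCACCGGTAGACGCATTGTGAGGGCACGGATCAGTGGATGGTCTCATGGGCGCGCCTTGCTGGGTCCTATGTCTTTAAAACCTACAGGGATTAGTATCACTCTATAGCAATGGTTAGTACTCAAGACCCAGGATACTCAAGAGGGATGCGATAGTTGAGATAACGGCGATTTCCACCTGAGCAGATCCTAAGCGTTCCTACATCGGGATCCATGGTCTATGGGGCACTTCTCAAGTGCTGCGTAGATTACCCCGTCGCAAAGACACGAGTGGGAAACTGGATGGGTTGGCAGTGGTCCCATTCATGACGTAATAAGCTCTCAAGTTAGCCGTAGCCAATCCTCCATAAGGTTAACGCAAGCGGTCCTCTTCCACTGGTGTAAGATACTATCATGTCGGCAGATGCGGGGAGTTTTTGAGAGTTG
    copies: 30
    divergence: 0.03
panel:
- family: satA
  sequence: TCTCAGGAGCGATATTATGTCACTTAATACGTGACTGATCCGTCATTTCTTCAGACCTAAGTGGGTGGGGGATCTACCCAGGCACATACCTGTGAGGTAATTCAGATACGTACGACTAACGGCGACCGAGTCACTACCTGCGAGATTGGT
- family: lineB
  sequence: ACAATTAGTAATCGGTTCTTCTGGAATCTCCTGTGAGAGTACGAGATCGCCGGGTTCCGGCGCTTACGGCGTTGGCGAAAGATTCGTATTTTACTTCTGGAGCCAGCGATTATCCGGATTCCGGTATCTCAGAACTTTCATCAACGCTGCCACAGAGGTTCACTCACTACTAGCGTGCACCGGTAGACGCATTGTGAGGGCACGGATCAGTGGATGGTCTCATGGGCGCGCCTTGCTGGGTCCTATGTCTTTAAAACCTACAGGGATTAGTATCACTCTATAGCAATGGTTAGTACTCAAGACCCAGGATACTCAAGAGGGATGCGATAGTTGAGATAACGGCGATTTCCACCTGAGCAGATCCTAAGCGTTCCTACATCGGGATCCATGGTCTATGGGG
thresholds:
  min_identity: 0.8
  min_overlap_bp: 100.0
microsat:
  unit_min: 2
  unit_max: 4
  min_units: 3
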
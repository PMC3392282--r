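# Worked example: three differentiated populations and a 0.2:0.6:0.2
# admixture of them. Frequency-level parameters; the lower triangle of the
# frequency variance-covariance matrix is listed row by row.
populations:
  - {name: P1, mu: 0.4, n: 9000}
  - {name: P2, mu: 0.4, n: 8000}
  - {name: P3, mu: 0.4, n: 7000}
C:
  - [0.1]
  - [0.01, 0.1]
  - [0.04, 0.09, 0.1]
admixed:
  - {name: P4, parents: [P1, P2, P3], proportions: [0.2, 0.6, 0.2], n: 10000}
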
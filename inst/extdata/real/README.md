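# Reference inputs (not distributed)

The reference-data checks in the test suite and the worked examples on
real structures expect the published inputs in this directory. They are
not distributed with the package (size and licensing); drop them in
under these names to enable the checks:

- `1VAO_dimer.pdb` — a two-chain assembly of PDB entry 1VAO (vanillyl
  alcohol oxidase dimer), e.g. the first two chains of the deposited
  asymmetric unit.
- `MSA_VAO.fa`, `MSA_EUGO.fa`, `MSA_PCMH.fa` — the three single-subfamily
  alignments (VAO-like, EUGO-like, PCMH-like sequences).
- `MSA_all.fa` — the merged three-subfamily alignment.
- `subfamily_labels.tsv` — two columns (`id`, `label`) assigning each
  `MSA_all.fa` record to VAO / EUGO / PCMH, e.g. by membership in the
  three single-subfamily files.

Without these files the corresponding checks fail with a pointer to this
README; everything else in the package runs on generated data.
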
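# Demo pipeline configuration: simulate a study-sized dataset and run
# every stage. Paths in an `input` block would replace the simulate
# block for real data:
#   input:
#     tree: tree.nwk
#     counts: counts.tsv
#     lineages: lineages.tsv
#     libraries: libraries.tsv
#     totals: totals.tsv
simulate:
  seed: 1
  beta: 3
analysis:
  threshold: 500
  thresholds: [300, 500, 1000, 1500]
  epsilon: 1
  resamples: 10000
  seed: 1
  log_scale: false
  proxy: asr
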
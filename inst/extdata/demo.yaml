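# Demonstration pipeline configuration: simulate the synthetic
# asthma-biologics reporting universe with the package's default catalogs
# and planted associations, screen every drug, and summarize the
# ear-and-labyrinth subset.
simulate:
  n_reports: 60000
  seed: 42
  drugs: default
  events: default
  planted: default
screen:
  background: all_reports
  criteria:
    min_reports: 3
    prr_min: 2
    ror_min: 2
    ic025_min: 0
    ic025_strict: true
summarize:
  subset_soc: Ear and labyrinth disorders
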
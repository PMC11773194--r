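# Packaged data files

- `daphnia_culture_log.csv` — data-capture template for monitoring the health
  and performance of running *Daphnia magna* cultures: daily per-jar animal
  counts, offspring observations, food ration (mL of algal suspension) and
  medium-change flags over the first sixteen days of a culture. Attached by
  the `daphnia_culture` example map as the resource behind its culture-log
  raw-data node; it is attachment data and is never parsed analytically.
- `profile-example.yaml` — example validation-profile config file consumed by
  `profile_from_config()`.
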
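# Example and user-supplied data

- `synthetic_census.csv` (+ `_species`, `_dts`, `_units` sidecars): a small
  SYNTHETIC leaf census written by `generate_census()` (5 stratigraphic
  levels, 270 leaves, 25-species pool, seed 2468). It exists so examples
  and the README can run without any real specimen data; it is not a real
  census.
- `deposited/`: not shipped. To replicate the published census numbers,
  obtain the journal-deposited leaf-and-damage dataset, convert it to CSV
  with registry sidecars in the `write_census()` layout, and place it at
  `deposited/leaf_damage_census.csv` (plus `leaf_damage_census_species.csv`,
  `_dts.csv`, `_units.csv`). The replication test in
  `tests/testthat/test-acceptance.R` then runs against it.
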
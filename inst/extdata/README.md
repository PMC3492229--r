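# Synthetic parameter tables

All files here are **synthetic stand-ins**, generated by
`make_fixture_tables()` (see `R/synthetic_data.R`); a test asserts the files
match the generator so they cannot drift. They are *shaped like* their
real-world counterparts but are not measured data:

- `other_cause_mortality_synthetic.csv` — annual all-cause (non-breast-cancer)
  death probability by age; Gompertz curve shaped like US life tables.
- `treated_bc_mortality_invasive_synthetic.csv` — annual death probability
  given invasive breast cancer under treatment, by age.
- `expected_life_invasive_synthetic.csv`, `expected_life_dcis_synthetic.csv`
  — post-diagnosis expected remaining life years by age (SEER-survival
  shape, cure-inclusive; DCIS dominates invasive at every age).
- `terminal_reward_synthetic.csv` — expected remaining life years at the
  terminal model age (100).

Format: headered CSV `age,value`, ages 40..100.
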
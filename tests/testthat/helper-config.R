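# Shared fixtures: the bundled published configuration (printed values) and
# its effective base case (range-implied values substituted).
base_cfg <- base_case_config()
eff_cfg <- effective_base_case(base_cfg)

# Observed counts of the source trial: 14/304 and 33/298 proven/probable IFI,
# 5/14 and 16/33 IFI-related deaths, 44/290 and 51/265 other-cause deaths.
trial_counts_published <- data.frame(
  arm = c("posaconazole", "sat"), n = c(304L, 298L),
  n_ifi = c(14L, 33L), n_death_ifi = c(5L, 16L),
  n_death_other = c(44L, 51L), stringsAsFactors = FALSE)
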
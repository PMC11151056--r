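# shared panels and small simulation setups used across test files

# one channel, two Tm classes (stepwise melting design, imaged at 58/68 degC)
dual_tm_panel <- function() {
  assay_panel(
    rbind(target_spec("LOW", "FAM", 63), target_spec("HIGH", "FAM", 73)),
    channels = "FAM", temperatures = c(58, 68)
  )
}

# single direct target, single temperature
mono_panel <- function() {
  assay_panel(target_spec("T1", "FAM", 73), "FAM", 58)
}

# quadruplex mutation panel: total-template channel, one drop-off variant
# (wildtype probe on HEX), two direct variant channels
quadruplex_panel <- function() {
  assay_panel(
    rbind(
      target_spec("TOTAL", "ROX", 73),
      target_spec("WT19", "HEX", 73),
      target_spec("DEL19", "ROX", 73.5, rule = "drop_off",
                  ref_channel = "ROX", wt_channel = "HEX"),
      target_spec("T790M", "FAM", 73),
      target_spec("L858R", "VIC", 73)
    ),
    channels = c("ROX", "HEX", "FAM", "VIC"), temperatures = 58
  )
}

# occupancy-level well: counts at each panel temperature for one channel
channel_counts <- function(occ, panel, channel) {
  purrr::map_dfr(panel$temperatures, function(temp) {
    calls <- true_calls(occ, panel, temp)[[channel]]
    partition_counts(length(calls), sum(!calls), temperature = temp)
  })
}
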
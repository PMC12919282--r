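# Shared fixture builders: everything is generated in code at test time.

# Single-hotspot, single-cell config with a reduced species pool; fast
# enough to regenerate hundreds of times in simulation-based tests.
small_cfg <- function(seed = 1L, cells = 1L, ...) {
  sim_config(n_hotspots = 1L, cells_per_hotspot = cells, n_species = 40L,
             seed = seed, ...)
}

# Latent monthly panel relabelled with the analysis-side column names, so
# model fits can be checked directly against the generating truth without
# the checklist realization layer.
truth_panel <- function(cfg) {
  pan <- sim_monthly_panel(cfg)$panel
  pan$bud_count <- pan$bud
  pan$richness_all <- pan$richness_all_true
  pan$richness_water <- pan$richness_water_true
  pan <- do.call(rbind, lapply(split(pan, pan$hotspot_id), function(p) {
    p <- p[order(p$month_index), ]
    p$wet_pct <- p$wet_pct_true
    p$wet_pct_lag1 <- c(NA, p$wet_pct[-nrow(p)])
    p
  }))
  rownames(pan) <- NULL
  pan
}

# Tiny hand-rolled checklist table: one row per (checklist, species).
make_checklists <- function(birder, hotspot, date, species_lists,
                            id_prefix = "cl") {
  rows <- list()
  for (i in seq_along(birder)) {
    sp <- species_lists[[i]]
    rows[[i]] <- data.frame(
      checklist_id = sprintf("%s%03d", id_prefix, i),
      birder_id = birder[i], hotspot_id = hotspot[i],
      date = as.Date(date[i]), species = sp)
  }
  do.call(rbind, rows)
}

EPOCH <- as.Date("2013-04-01")

# internal helpers exercised directly in tests
date_month_index <- budwatch:::date_month_index
is_count <- budwatch:::is_count

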
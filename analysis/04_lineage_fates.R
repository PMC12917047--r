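#!/usr/bin/env Rscript
# Lineage analysis of the corrected lineage scenes: cell-cycle timing per
# generation, division-mode classification from daughter MYOG fates,
# division orientation, differentiation/proliferation indexes, and MYOG
# onset / re-division statistics.

library(musctrack)
library(dplyr)

lin_dirs <- grep("_lineage$",
                 list.dirs("results/scenes", recursive = FALSE),
                 value = TRUE)

all_div <- list(); all_idx <- list()
for (d in lin_dirs) {
  genotype <- sub("_.*", "", basename(d))
  ts <- read_tracks_csv(file.path(d, "tracks_corrected.csv"))

  div <- division_records(ts, fate_mode = "endpoint")
  div$genotype <- genotype
  all_div[[genotype]] <- div
  mf <- division_mode_fractions(div)

  dur <- mean_cycle_durations(cell_cycle_durations(ts))
  di <- differentiation_index(ts, fate_mode = "endpoint")
  pi_ <- proliferation_index(ts)
  mr <- myog_onset_and_redivision(ts)

  cat(sprintf("\n== %s ==\n", genotype))
  cat(sprintf("  divisions: %d  (ACD %.1f%%, SCDd %.1f%%, SCDp %.1f%%)\n",
              sum(mf$n), 100 * mf$fraction[mf$mode == "ACD"],
              100 * mf$fraction[mf$mode == "SCDd"],
              100 * mf$fraction[mf$mode == "SCDp"]))
  cat(sprintf("  first division %.1f h (n=%d); later cycles %.1f h (n=%d)\n",
              dur$mean_h[dur$generation_group == "1"],
              dur$n[dur$generation_group == "1"],
              dur$mean_h[dur$generation_group == ">=2"],
              dur$n[dur$generation_group == ">=2"]))
  cat(sprintf("  differentiation index %.2f (n=%d), proliferation index %.2f\n",
              di$index, di$n_known, pi_$index))
  cat(sprintf("  MYOG onset %.1f h post-mitosis; %.1f%% of positives re-divide; %.1f%% of SCDd from negative mothers\n",
              mean(mr$onset_delays_h), 100 * mr$redivision$fraction,
              100 * mr$scdd_from_negative_mother$fraction))

  all_idx[[genotype]] <- tibble::tibble(
    genotype = genotype,
    differentiation_index = di$index,
    proliferation_index = pi_$index,
    first_division_h = dur$mean_h[dur$generation_group == "1"],
    later_cycles_h = dur$mean_h[dur$generation_group == ">=2"],
    acd = mf$fraction[mf$mode == "ACD"],
    scdd = mf$fraction[mf$mode == "SCDd"],
    scdp = mf$fraction[mf$mode == "SCDp"])
}

write.csv(bind_rows(all_div), "results/divisions.csv", row.names = FALSE)
write.csv(bind_rows(all_idx), "results/fate_indexes.csv", row.names = FALSE)
cat("\nwrote results/divisions.csv and results/fate_indexes.csv\n")
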
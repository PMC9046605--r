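# Shared fixtures, built in code.

# Random smooth per-joint angle programs within the gimbal-safe range.
random_programs <- function(max_amp = 30) {
  rand_prog <- function() {
    a <- stats::runif(3, -max_amp / 3, max_amp / 3)
    ph <- stats::runif(3, 0, 2 * pi)
    function(tau) a[1] * sin(pi * tau + ph[1]) + a[2] * sin(2 * pi * tau + ph[2]) +
      a[3] * cos(pi * tau + ph[3])
  }
  joint <- function() list(sagittal = rand_prog(), frontal = rand_prog(),
                           transverse = rand_prog())
  list(sha_cal = joint(), cal_mid = joint(), mid_met = joint(),
       met_hal = joint(), mla = function(tau) 135 + 6 * sin(pi * tau)^2)
}

# Minimal long outcomes table for mixed-model tests.
make_outcomes_table <- function(n_per_group, cell_means, cell_sds,
                                sigma_b = 2, seed = 1) {
  set.seed(seed)
  rows <- list()
  k <- 0
  for (g in c("IG", "CG")) {
    n <- n_per_group[[g]]
    for (i in seq_len(n)) {
      k <- k + 1
      b <- stats::rnorm(1, 0, sigma_b)
      for (tm in c("baseline", "week8")) {
        cell <- paste0(tolower(g), if (tm == "baseline") "_pre" else "_post")
        sd_t <- sqrt(max(cell_sds[[cell]]^2 - sigma_b^2, 0.01))
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sprintf("%s%03d", g, i), group = g, time = tm,
          outcome = "y",
          value = cell_means[[cell]] + b + stats::rnorm(1, 0, sd_t))
      }
    }
  }
  do.call(rbind, rows)
}
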
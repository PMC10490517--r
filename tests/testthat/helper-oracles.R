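# Independent closed-form layer arithmetic for the two architectures.
# Deliberately written from the layer tables, not from the package's
# builder, so it can serve as an oracle for the built networks.

oracle_time_chain <- function(t) {
  for (blk in 1:4) {
    t <- t - 4L        # valid conv, kernel 5, stride 1
    t <- t %/% 2L      # max-pool size 2, stride 2, floor
  }
  t
}

# one BD-Deep4 branch: temporal conv (25 @ 5x1), optional spatial conv
# (25 @ e x 1 over 25 maps), batch-norm affine pairs, then conv blocks of
# 50/100/200 with kernel 5 and batch-norm each
oracle_branch_params <- function(e, spatial) {
  p <- 5 * 25 + 25                       # temporal conv + bias
  if (spatial) p <- p + (e * 25) * 25 + 25
  p <- p + 2 * 25                        # batch-norm gamma/beta
  widths <- c(25, 50, 100, 200)
  for (i in 2:4) {
    p <- p + (5 * widths[i - 1]) * widths[i] + widths[i] + 2 * widths[i]
  }
  p
}

oracle_param_count <- function(arch, sensors, window = 600L) {
  n_ch <- switch(sensors, "eeg" = 6L, "eeg+spr" = 7L, "eeg+ecg" = 7L,
                 "eeg+spr+ecg" = 8L)
  flat <- oracle_time_chain(window) * 200L
  if (arch == "data_fusion") {
    oracle_branch_params(n_ch, spatial = TRUE) + flat * 2 + 2
  } else {
    n_single <- n_ch - 6L
    branches <- oracle_branch_params(6L, spatial = TRUE) +
      n_single * oracle_branch_params(1L, spatial = FALSE)
    concat <- (1L + n_single) * flat
    branches + concat * 500 + 500 + 500 * 2 + 2
  }
}
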
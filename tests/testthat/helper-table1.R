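# Printed energy-unit (W m-2) intensity bounds of the actinometer table,
# frozen for the printed-precision conversion checks. `unit` is the value
# of one unit in the last printed significant digit; a zero bound carries
# no precision information and is skipped. The Dronpa-2 500 nm upper
# bound is a documented outlier (printed 1.0e6, arithmetic ~3.1e6) and is
# excluded, as are the PA rows whose printed conversions are not
# 2-significant-figure rounds of the photon bounds.
table1_w_cells <- function() {
  rows <- list(
    list("Cin", 350, "upper", 5.5, 0.1),
    list("Cin", 365, "upper", 4.6, 0.1),
    list("Cin", 380, "upper", 5.3, 0.1),
    list("Cin", 405, "upper", 15, 1),
    list("Cin", 420, "upper", 37, 1),
    list("Nit", 365, "upper", 360, 10),
    list("Nit", 380, "upper", 230, 10),
    list("Nit", 405, "upper", 200, 10),
    list("Nit", 420, "upper", 340, 10),
    list("Dronpa-2", 445, "lower", 80, 1),
    list("Dronpa-2", 445, "upper", 4.8e6, 1e5),
    list("Dronpa-2", 480, "lower", 50, 1),
    list("Dronpa-2", 480, "upper", 2.5e6, 1e5),
    list("Dronpa-2", 500, "lower", 72, 1),
    list("DASA", 530, "lower", 18, 1),
    list("DASA", 530, "upper", 660, 10),
    list("DASA", 560, "lower", 9, 1),
    list("DASA", 560, "upper", 320, 10),
    list("DASA", 600, "lower", 4, 1),
    list("DASA", 600, "upper", 140, 10),
    list("DASA", 632, "lower", 4, 1),
    list("DASA", 632, "upper", 110, 10),
    list("DASA", 650, "lower", 6, 1),
    list("DASA", 650, "upper", 260, 10)
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(name = r[[1]], lambda = r[[2]], bound = r[[3]],
               printed_w = r[[4]], unit = r[[5]])
  }))
}

# a minimal hand-built tau_map for tests that need direct control
make_tau_map <- function(tau, r2 = NULL, mask = NULL) {
  tau <- as.matrix(tau)
  if (is.null(r2)) r2 <- matrix(1, nrow(tau), ncol(tau))
  if (is.null(mask)) mask <- is.finite(tau)
  structure(list(tau = tau, r_squared = r2, F0 = tau * 0 + 1,
                 F_inf = tau * 0, mask = mask,
                 timing = timing_model("widefield", frame_interval = 0.1),
                 binning = 1L, r2_threshold = 0.9, pixel_size_m = 1e-6),
            class = "tau_map")
}
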
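# Shared fixtures, built in code.

# Two-locus panel for hand-checkable cases.
tiny_panel <- function() locus_panel(list(L1 = c(100L, 102L, 104L, 106L),
                                          L2 = c(150L, 152L, 154L, 156L)))

# Small but complete array configuration: quick to simulate, still exercises
# every stage (parental + F2 classes, several bouts, noise on).
small_config <- function(pollinator = "butterfly", ...) {
  simulation_config(n_parental = 8L, n_f2 = 4L, grid = c(4L, 4L),
                    bout_model = list(mean_visits = 6,
                                      max_visits_per_flower = 2L),
                    transport = list(grains_per_pickup = 10L, d = 0.3,
                                     s = 0.4),
                    pollinator = pollinator, n_bouts = 4L, ...)
}

noise_free <- function() list(dropout = 0, contamination = 0, error = 0)

# Fixed thresholds for unit tests that are not about calibration.
fixed_thresholds <- function(relaxed = 0, strict = 2)
  structure(list(relaxed = relaxed, strict = strict,
                 summary = data.frame(level = c(0.80, 0.95),
                                      threshold = c(relaxed, strict),
                                      assignment_rate = NA, accuracy = NA),
                 calib = calibration_config()),
            class = "delta_thresholds")

# Cache one default-size simulated experiment per session for read-only
# tests (simulation is cheap; the cache just avoids repetition).
default_exp <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_experiment(simulation_config(),
                                                      seed = 11L)
    cache
  }
})

# Minimal standardized_design for direct sampler tests: iid standard-normal
# traits, known coefficients.
toy_design <- function(n = 150L, n_traits = 2L, b = NULL, g = NULL,
                       alpha = 0.5, tau_bout = 0.2, tau_genet = 0.2,
                       n_bout = 6L, n_genet = 25L, seed = 1L) {
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * n_traits), n, n_traits)
  Z <- scale(Z)
  if (is.null(b)) b <- stats::rnorm(n_traits, 0, 0.3)
  if (is.null(g)) g <- stats::rnorm(n_traits, 0, 0.2)
  bout <- sample.int(n_bout, n, replace = TRUE)
  genet <- sample.int(n_genet, n, replace = TRUE)
  r <- stats::rnorm(n_bout, 0, tau_bout)
  rp <- stats::rnorm(n_genet, 0, tau_genet)
  eta <- alpha + Z %*% b + (Z^2) %*% g + r[bout] + rp[genet]
  y <- stats::rpois(n, exp(pmin(eta, 6)))
  X <- cbind(alpha = 1, Z, Z^2)
  colnames(X) <- c("alpha", paste0("beta_t", seq_len(n_traits)),
                   paste0("gamma_t", seq_len(n_traits)))
  structure(list(y = y, X = X, bout = bout, genet = genet,
                 bout_levels = as.character(seq_len(n_bout)),
                 genet_levels = as.character(seq_len(n_genet)),
                 spec = model_spec("visits", "butterfly"),
                 transform = list(trait_range = apply(Z, 2, range)),
                 truth = list(alpha = alpha, b = b, g = g)),
            class = "standardized_design")
}
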
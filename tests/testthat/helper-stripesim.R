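# Shared fixtures and small test utilities.
#
# Heavyweight objects (simulated stacks, OTFs) are computed once per test run
# and cached in an environment; consumers treat them as read-only.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- expr
  .fixtures[[name]]
}

# The paper-default optical system: NA 1.4, 520 nm emission, 45 nm pixels.
default_sys <- function(shape) optical_system(1.4, 520, 45, shape)

default_otf <- function(shape) {
  fixture(paste0("otf_", paste(shape, collapse = "x")),
          analytic_otf(default_sys(shape), shape))
}

# Noiseless stack of Gaussian-blurred beads under default illumination.
bead_stack <- function(shape = c(128L, 128L), seed = 1L, n = 60L,
                       blur_sigma = 2) {
  key <- sprintf("stack_%s_%d_%d_%g", paste(shape, collapse = "x"),
                 seed, n, blur_sigma)
  fixture(key, {
    truth <- make_ground_truth("beads", shape, seed = seed, n = n,
                               blur_sigma = blur_sigma)
    simulate_stack(truth, default_sys(shape), seed = seed)
  })
}

# The estimator reports the positive-kx member of the +/- conjugate pair; the
# simulator's k may be the other one. Returns +1/-1 to map truth onto the
# estimate's convention (phases negate together with k).
align_sign <- function(k_est, k_true) if (sum(k_est * k_true) < 0) -1 else 1

# Angle difference modulo 180 degrees (stripe orientations are axial).
angle_diff_180 <- function(a_deg, b_deg) abs(((a_deg - b_deg + 90) %% 180) - 90)

deg <- function(rad) rad * 180 / pi
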
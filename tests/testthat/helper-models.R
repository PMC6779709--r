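# Shared fixtures built once per test run (all generated in code).
test_skel <- default_skeleton()
test_muscles <- default_muscles(test_skel)
test_surrogates <- build_surrogates(test_skel, test_muscles)
test_model <- gait_model(test_skel, test_muscles, test_surrogates,
                         contact_params(), default_contact_elements(test_skel))

# numeric Lagrangian of the planar skeleton (independent oracle for the
# dynamics residual): tau_i = d/dt dL/dqd_i - dL/dq_i by finite differences
lagrangian_tau <- function(skel, q, qd, qdd, h = 1e-5) {
  L <- function(q, qd) {
    fk <- gaitfes:::fk_batched(skel, gaitfes:::as_coord_array(q),
                               gaitfes:::as_coord_array(qd), NULL)
    e <- 0
    for (nm in names(skel$segments)) {
      sg <- skel$segments[[nm]]; k <- fk[[nm]]
      e <- e + 0.5 * sg$mass * (k$vcx[1, 1]^2 + k$vcy[1, 1]^2) +
        0.5 * sg$inertia * k$om[1, 1]^2 - sg$mass * skel$gravity * k$cy[1, 1]
    }
    e
  }
  n <- length(q)
  dLdqd <- function(q, qd) vapply(1:n, function(i) {
    e <- rep(0, n); e[i] <- h
    (L(q, qd + e) - L(q, qd - e)) / (2 * h)
  }, 0)
  dLdq <- vapply(1:n, function(i) {
    e <- rep(0, n); e[i] <- h
    (L(q + e, qd) - L(q - e, qd)) / (2 * h)
  }, 0)
  ddt <- vapply(1:n, function(i) {
    f <- function(eps) dLdqd(q + eps * qd, qd + eps * qdd)[i]
    (f(h) - f(-h)) / (2 * h)
  }, 0)
  ddt - dLdq
}
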
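# standard test parameters used throughout: a = 30, b = 2, c = 2,
# equilibrium u* = ln(15)/2, b u* = ln(15) > 2 (conditionally stable at
# alpha = 1)
std_params <- blowfly_params(a = 30, b = 2, c = 2)

# random valid parameter sets (a > c), reproducible
random_params <- function(n, seed = 42L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    c_ <- runif(1, 0.1, 5)
    blowfly_params(a = c_ * exp(runif(1, 0.05, 4)), b = runif(1, 0.1, 5),
                   c = c_)
  })
}

# analytic m = 1 critical delay: for a degree-2 trinomial with a complex
# root pair on the unit circle the root product equals -a1_tilde = 1
analytic_tau0_m1 <- function(params, alpha, kind) {
  ac <- alpha * params$c
  L <- (1 - alpha) / ac
  s <- params$b_u_star - 1 - L   # -a1_tilde = (1-E) * s  (nsfd), tau*ac*s (euler)
  if (kind == "nsfd") -log(1 - 1 / s) / ac else 1 / (ac * s)
}
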
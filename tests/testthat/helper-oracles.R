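# Shared helpers: the frozen reference configuration (cached per run)
# and an independent flux-summation oracle for the full model built by
# enumerating every reaction's stoichiometry times its mass-action rate.

frozen_test_config <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- frozen_config()
    cfg
  }
})

frozen_test_params <- function() frozen_test_config()$params

# stoichiometry x rate tabulation over the six reactions plus the basal
# relaxation terms; written independently of full_rhs() on purpose
oracle_full_rhs <- function(state, p, U) {
  X <- state[["X"]]; XP <- state[["XP"]]; YP <- state[["YP"]]
  C1 <- state[["C1"]]; C2 <- state[["C2"]]; C3 <- state[["C3"]]
  Y <- p$YT - YP - C2 - C3
  # columns: X, XP, YP, C1, C2, C3, Y(implied, for the conservation check)
  rxn <- list(
    list(rate = p$k10 * X * U,    st = c(-1,  1, 0,  0,  0,  0,  0)),
    list(rate = p$k1010 * XP,     st = c( 1, -1, 0,  0,  0,  0,  0)),
    list(rate = p$k1 * X * XP,    st = c(-1, -1, 0,  1,  0,  0,  0)),
    list(rate = p$k2 * C1,        st = c( 1,  1, 0, -1,  0,  0,  0)),
    list(rate = p$k3 * C1,        st = c( 0,  2, 0, -1,  0,  0,  0)),
    list(rate = p$k4 * XP * p$P,  st = c( 1, -1, 0,  0,  0,  0,  0)),
    list(rate = p$k5 * Y * XP,    st = c( 0, -1, 0,  0,  1,  0, -1)),
    list(rate = p$k55 * C2,       st = c( 0,  1, 0,  0, -1,  0,  1)),
    list(rate = p$k6 * C2,        st = c( 0,  1, 1,  0, -1,  0,  0)),
    list(rate = p$k7 * YP * p$P,  st = c( 0,  0, -1, 0,  0,  0,  1)),
    list(rate = p$k8 * YP * p$T,  st = c( 0,  0, -1, 0,  0,  1,  0)),
    list(rate = p$k88 * C3,       st = c( 0,  0,  1, 0,  0, -1,  0)),
    list(rate = p$k9 * C3,        st = c( 1,  0,  1, 0,  0, -1,  0))
  )
  d <- Reduce(`+`, lapply(rxn, function(r) r$rate * r$st))
  d[1] <- d[1] - p$lambda2 * (X - p$Xbasal)
  d[2] <- d[2] - p$lambda1 * (XP - p$XPbasal)
  stats::setNames(d, c("X", "XP", "YP", "C1", "C2", "C3", "Y"))
}

random_full_state <- function(p, scale = 10) {
  s <- stats::runif(6) * c(scale, scale, p$YT / 3, scale / 5, p$YT / 6,
                           p$YT / 6)
  stats::setNames(s, c("X", "XP", "YP", "C1", "C2", "C3"))
}
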
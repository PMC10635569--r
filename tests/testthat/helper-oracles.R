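# Independent oracles and micro-fixtures shared across tests.
#
# enum_lp() solves small LPs by exhaustive vertex enumeration of the
# polytope {S v = b, lb <= v <= ub}: every basic solution is generated by
# choosing rank(S) basic columns and pinning the remaining variables to a
# bound. It shares no code with the package's simplex.

enum_lp <- function(obj, A, b, lb, ub, dir = "max") {
  A <- as.matrix(A)
  n <- ncol(A)
  r <- qr(A)$rank
  best <- NA_real_
  subsets <- if (r == 0) list(integer()) else utils::combn(n, r, simplify = FALSE)
  for (B in subsets) {
    if (r > 0) {
      AB <- A[, B, drop = FALSE]
      if (qr(AB)$rank < r) next
    }
    Nn <- setdiff(seq_len(n), B)
    k <- length(Nn)
    for (mask in 0:(2^k - 1)) {
      xN <- ifelse(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0, ub[Nn], lb[Nn])
      x <- numeric(n)
      x[Nn] <- xN
      if (r > 0) {
        rhs <- b - as.vector(A[, Nn, drop = FALSE] %*% xN)
        xB <- tryCatch(qr.solve(A[, B, drop = FALSE], rhs),
                       error = function(e) NULL)
        if (is.null(xB)) next
        x[B] <- xB
      }
      if (max(abs(A %*% x - b)) > 1e-7) next
      if (any(x < lb - 1e-7) || any(x > ub + 1e-7)) next
      v <- sum(obj * x)
      if (is.na(best) || (dir == "max" && v > best) ||
          (dir == "min" && v < best)) {
        best <- v
      }
    }
  }
  best
}

# The classic hand-LP chain: uptake capped at 10, one doubling step, a
# biomass sink. Optimum = 20.
toy_chain_model <- function(uptake = 10) {
  m <- empty_model("toy_chain")
  m <- add_metabolites(m, c("s_e", "s_c", "p_c"),
                       formula = c("C6H12O6", "C6H12O6", "C3H6O3"))
  m <- add_reaction(m, "EX_s_e", c(s_e = -1), lb = -uptake, ub = 1000)
  m <- add_reaction(m, "St", "s_e --> s_c", gpr = "g_t")
  m <- add_reaction(m, "SPLIT", "s_c --> 2 p_c", gpr = "g_s")
  m <- add_reaction(m, "BIO", c(p_c = -1), kind = "biomass", lb = 0, ub = 1000)
  set_objective(m, "BIO")
}

# A chain with a duplicated internal step: at fraction 1 each duplicate
# ranges over [0, total] while their sum is pinned.
parallel_path_model <- function(uptake = 10) {
  m <- toy_chain_model(uptake)
  add_reaction(m, "SPLIT_DUP", "s_c --> 2 p_c", gpr = "g_s2")
}

# Minimal ATP-driven fermenter for maintenance arithmetic: one catabolic
# reaction with ATP yield y, biomass = pure GAM hydrolysis, so
# mu = (y * U - ngam) / gam. Tiny (9 reactions) => millisecond LPs.
mini_atp_toy <- function(y = 4, gam = 30, ngam = 5, uptake = 10) {
  m <- empty_model("mini_atp")
  m <- add_metabolites(m, c("s_e", "s_c", "p_e", "p_c", "h2o_e", "h2o_c",
                            "atp_c", "adp_c", "pi_c", "h_c", "h_e"),
                       formula = c("C6H12O6", "C6H12O6", "C3H6O3", "C3H6O3",
                                   "H2O", "H2O", "C10H16N5O13P3",
                                   "C10H15N5O10P2", "H3PO4", "H", "H"))
  m <- add_reaction(m, "EX_s_e", c(s_e = -1), lb = -uptake, ub = 1000)
  m <- add_reaction(m, "EX_p_e", c(p_e = -1), lb = 0, ub = 1000)
  m <- add_reaction(m, "EX_h2o_e", c(h2o_e = -1), lb = -1000, ub = 1000)
  m <- add_reaction(m, "EX_h_e", c(h_e = -1), lb = 0, ub = 1000)
  m <- add_reaction(m, "St", "s_e --> s_c")
  m <- add_reaction(m, "Pt", "p_c --> p_e")
  m <- add_reaction(m, "Ht", "h_c --> h_e")
  m <- add_reaction(m, "H2Ot", "h2o_e <=> h2o_c", lb = -1000)
  st <- stats::setNames(c(-1, 2, -y, -y, y, y),
                        c("s_c", "p_c", "adp_c", "pi_c", "atp_c", "h2o_c"))
  m <- add_reaction(m, "CAT", st, name = sprintf("catabolism (%g ATP)", y))
  m <- add_reaction(m, "BIOMASS", stats::setNames(numeric(0), character(0)),
                    kind = "biomass")
  m <- set_objective(m, "BIOMASS")
  attr(m, "gam") <- 0
  set_maintenance(m, gam = gam, ngam = ngam)
}

# mini_atp_toy's media, varying only the uptake cap
mini_media <- function(uptakes) {
  out <- lapply(uptakes, function(u) {
    medium_spec(c(EX_s_e = u, EX_h2o_e = 1000))
  })
  names(out) <- sprintf("U%g", uptakes)
  out
}

# seeded random stoichiometry-like LPs (n <= 8) for the oracle suite
random_small_lp <- function(seed) {
  set.seed(seed)
  n <- sample(4:8, 1)
  m <- sample(2:4, 1)
  A <- matrix(sample(c(-2, -1, 0, 0, 1, 2), m * n, replace = TRUE), m, n)
  lb <- sample(c(-10, 0, 0), n, replace = TRUE)
  ub <- lb + sample(c(5, 10, 20), n, replace = TRUE)
  obj <- round(stats::rnorm(n), 2)
  list(obj = obj, A = A, b = rep(0, m), lb = lb, ub = ub)
}
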
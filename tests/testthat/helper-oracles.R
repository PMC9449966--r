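# Independent brute-force oracles, kept deliberately naive (explicit loops,
# definitional formulas) so they share no code with the package internals.

# definitional RBD sums of squares for a g x r cell matrix
brute_rbd_ss <- function(m) {
  g <- nrow(m); r <- ncol(m)
  grand <- sum(m) / (g * r)
  ss_g <- 0
  for (i in seq_len(g)) ss_g <- ss_g + r * (mean(m[i, ]) - grand)^2
  ss_r <- 0
  for (j in seq_len(r)) ss_r <- ss_r + g * (mean(m[, j]) - grand)^2
  ss_e <- 0
  for (i in seq_len(g)) {
    for (j in seq_len(r)) {
      ss_e <- ss_e + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + grand)^2
    }
  }
  list(ss_genotype = ss_g, ss_replication = ss_r, ss_error = ss_e,
       ss_total = ss_g + ss_r + ss_e)
}

# definitional RBD cross-products for two matched cell matrices
brute_rbd_sp <- function(mx, my) {
  g <- nrow(mx); r <- ncol(mx)
  gx <- sum(mx) / (g * r); gy <- sum(my) / (g * r)
  sp_g <- 0
  for (i in seq_len(g)) {
    sp_g <- sp_g + r * (mean(mx[i, ]) - gx) * (mean(my[i, ]) - gy)
  }
  sp_r <- 0
  for (j in seq_len(r)) {
    sp_r <- sp_r + g * (mean(mx[, j]) - gx) * (mean(my[, j]) - gy)
  }
  sp_e <- 0
  for (i in seq_len(g)) {
    for (j in seq_len(r)) {
      sp_e <- sp_e + (mx[i, j] - mean(mx[i, ]) - mean(mx[, j]) + gx) *
        (my[i, j] - mean(my[i, ]) - mean(my[, j]) + gy)
    }
  }
  list(sp_genotype = sp_g, sp_replication = sp_r, sp_error = sp_e)
}

# hand-rolled Gauss-Jordan elimination with partial pivoting
brute_solve <- function(A, b) {
  n <- nrow(A)
  M <- cbind(A, b)
  for (col in seq_len(n)) {
    piv <- which.max(abs(M[col:n, col])) + col - 1
    if (abs(M[piv, col]) < 1e-14) stop("singular")
    if (piv != col) M[c(col, piv), ] <- M[c(piv, col), ]
    M[col, ] <- M[col, ] / M[col, col]
    for (row in seq_len(n)) {
      if (row != col) M[row, ] <- M[row, ] - M[row, col] * M[col, ]
    }
  }
  unname(M[, n + 1])
}

# Duncan step-down by its textbook definition: a pair is non-significant
# iff some ordered subset containing both means has range <= its LSR
brute_duncan_sig <- function(m_sorted, lsr) {
  g <- length(m_sorted)
  sig <- matrix(FALSE, g, g,
                dimnames = list(names(m_sorted), names(m_sorted)))
  for (i in seq_len(g - 1)) {
    for (j in seq(i + 1, g)) {
      significant <- TRUE
      for (a in seq_len(i)) {
        for (b in seq(j, g)) {
          span <- b - a + 1
          if (m_sorted[a] - m_sorted[b] <=
              lsr[span - 1] + 1e-12 * max(1, abs(m_sorted[a]))) {
            significant <- FALSE
          }
        }
      }
      sig[i, j] <- sig[j, i] <- significant
    }
  }
  sig
}

# do two items share at least one letter?
letters_share <- function(l1, l2) {
  length(intersect(strsplit(l1, "")[[1]], strsplit(l2, "")[[1]])) > 0
}

# tiny balanced trial from a g x r value matrix, one trait
grid_trial <- function(m, trait = "y", year = "y1") {
  g <- nrow(m); r <- ncol(m)
  clonal_trial(data.frame(
    clone = rep(sprintf("G%02d", seq_len(g)), times = r),
    replication = rep(seq_len(r), each = g),
    year = year, trait = trait, value = as.vector(m),
    stringsAsFactors = FALSE))
}

# two-trait trial from matched matrices
grid_trial2 <- function(mx, my, traits = c("x", "y"), year = "y1") {
  g <- nrow(mx); r <- ncol(mx)
  clonal_trial(data.frame(
    clone = rep(rep(sprintf("G%02d", seq_len(g)), times = r), 2),
    replication = rep(rep(seq_len(r), each = g), 2),
    year = year,
    trait = rep(traits, each = g * r),
    value = c(as.vector(mx), as.vector(my)),
    stringsAsFactors = FALSE))
}
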
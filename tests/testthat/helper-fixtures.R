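# shared fixtures and reference implementations

# parameter sets of the CDF-validation panels (the published fourth panel
# lists a subcritical wild type and is excluded by construction)
cdf_validation_panels <- function() {
  tibble::tibble(
    panel = c("a", "b", "c"),
    b = 0.14, d = 0.13, c = c(1.7, 1.5, 1.5),
    u = c(1e-5, 1e-4, 1e-5)
  )
}

panel_params <- function(row, M) {
  branching_params(b = row$b, d = row$d, b1 = row$b,
                   d1 = row$b - row$c * (row$b - row$d), u = row$u, M = M)
}

# Naive single-site-updating reference for the lattice model: pure growth
# (d = d1 = 0, no mutation) on the 6-neighbor cubic lattice, recomputing
# every cell's empty-neighbor count from scratch at every event. Returns the
# total time to grow from 1 cell to n_final cells.
naive_lattice_growth_time <- function(n_final, b = 1) {
  occ <- new.env(parent = emptyenv())
  key <- function(p) paste(p, collapse = ",")
  nbrs <- function(p) {
    lapply(1:6, function(j) {
      d <- c(0, 0, 0)
      d[(j + 1) %/% 2] <- if (j %% 2 == 1) 1L else -1L
      p + d
    })
  }
  cells <- list(c(0L, 0L, 0L))
  assign(key(cells[[1]]), TRUE, envir = occ)
  t <- 0
  while (length(cells) < n_final) {
    empties <- lapply(cells, function(p) {
      Filter(function(q) !exists(key(q), envir = occ), nbrs(p))
    })
    w <- vapply(empties, length, integer(1))
    rate <- b * sum(w) / 6
    t <- t + stats::rexp(1, rate)
    i <- sample.int(length(cells), 1, prob = w)
    q <- empties[[i]][[sample.int(w[i], 1)]]
    assign(key(q), TRUE, envir = occ)
    cells[[length(cells) + 1]] <- q
  }
  t
}
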
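# Shared fixtures and memoized expensive computations.  The error-free
# solves are deterministic under their seeds, so caching them across test
# files only saves time, not coverage.

.memo <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

memo <- function(key, expr) {
  if (is.null(.memo[[key]])) .memo[[key]] <- force(expr)
  .memo[[key]]
}

ab_network <- function() {
  parse_network_text("A <-> B ; k1_2, k2_1",
                     rate_values = c(k1_2 = 2, k2_1 = 3))
}

protein_fx <- function() memo("protein_fx", protein_activation_fixture())
toggle_fx <- function() memo("toggle_fx", toggle_switch_fixture())

protein_ef <- function() memo("protein_ef", {
  solve_error_free(fixture_problem(protein_fx(), seed = 7))
})

toggle_ef <- function() memo("toggle_ef", {
  solve_error_free(fixture_problem(toggle_fx(), seed = 7))
})

# a random reversible (hence t = l) mass-action network
random_reversible_network <- function(seed) {
  set.seed(seed)
  m <- sample(2:4, 1)
  species <- LETTERS[seq_len(m)]
  n_cx <- sample(3:5, 1)
  complexes <- list()
  keys <- character(0)
  while (length(complexes) < n_cx) {
    size <- sample(0:2, 1)
    cx <- if (size == 0) numeric(0) else {
      picks <- sample(species, size, replace = TRUE)
      tab <- table(picks)
      stats::setNames(as.numeric(tab), names(tab))
    }
    key <- paste(sprintf("%g%s", cx, names(cx)), collapse = "+")
    if (key %in% keys) next
    complexes[[length(complexes) + 1L]] <- cx
    keys <- c(keys, key)
  }
  used <- unique(unlist(lapply(complexes, names)))
  missing_sp <- setdiff(species, used)
  for (sp in missing_sp) {
    complexes[[length(complexes) + 1L]] <- stats::setNames(1, sp)
  }
  n <- length(complexes)
  n_pairs <- sample(2:4, 1)
  rows <- list()
  lab <- 0L
  for (i in seq_len(n_pairs)) {
    fr <- sample(n, 1); to <- sample(setdiff(seq_len(n), fr), 1)
    lab <- lab + 1L
    rows[[length(rows) + 1L]] <- data.frame(from = fr, to = to,
                                            label = sprintf("kf%d", lab))
    rows[[length(rows) + 1L]] <- data.frame(from = to, to = fr,
                                            label = sprintf("kr%d", lab))
  }
  rx <- unique(do.call(rbind, rows))
  rx <- rx[!duplicated(rx[, c("from", "to")]), ]
  k <- stats::setNames(exp(stats::rnorm(nrow(rx))), rx$label)
  reaction_network(species, complexes, rx, k)
}
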
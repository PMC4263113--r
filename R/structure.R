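#' Structural decomposition of a reaction network
#'
#' Computes every matrix and index of Chemical Reaction Network Theory that
#' the downstream manifold, continuation and inverse modules rely on: the
#' molecularity matrix \eqn{Y} (m x n), the stoichiometric matrix \eqn{N}
#' (m x r), the linkage-class indicator \eqn{\Lambda} (n x l), the terminal
#' strong linkage classes, the integers \eqn{l, t, s, \delta, \lambda}, a
#' basis \eqn{B} of the conservation laws (left null space of \eqn{YA}) and
#' a basis \eqn{\omega} of the deficiency subspace
#' \eqn{Ker(Y) \cap Im(A) = Ker[Y; \Lambda^T]}.
#'
#' The deficiency is \eqn{\delta = n - l - s} and the equilibrium-manifold
#' dimension is \eqn{\lambda = m - s}.  Networks with more terminal strong
#' linkage classes than linkage classes (t > l) are refused: the tangency
#' theory implemented here covers t = l networks only.
#'
#' Both \eqn{B} and \eqn{\omega} are integerized when possible (e.g. the
#' conservation law E + ES + ESS prints with unit coefficients), with the
#' leading nonzero coefficient positive, so that conservation constants taken
#' from experiments can be used directly as right-hand sides \eqn{B^T c = b}.
#'
#' @param net a [reaction_network()].
#' @return An object of class `structural_summary` with fields `Y`, `N`,
#'   `incidence`, `Lambda`, `linkage_classes`,
#'   `terminal_strong_linkage_classes`, `ell`, `t`, `s`, `delta`, `lambda`,
#'   `B`, `omega`, and `conservation_laws` (pretty-printed strings).
#' @examples
#' net <- parse_network_text("A <-> B ; k1_2, k2_1")
#' structural_summary(net)
#' @export
structural_summary <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  m <- length(net$species); n <- length(net$complexes)
  r <- nrow(net$reactions)
  if (n == 0L || r == 0L) stop("empty network")

  Y <- matrix(0, m, n, dimnames = list(net$species, NULL))
  for (j in seq_len(n)) {
    cx <- net$complexes[[j]]
    if (length(cx)) Y[names(cx), j] <- cx
  }

  # incidence matrix of the graph of complexes (n x r)
  Ia <- matrix(0, n, r)
  for (i in seq_len(r)) {
    Ia[net$reactions$from[i], i] <- -1
    Ia[net$reactions$to[i], i] <- 1
  }
  N <- Y %*% Ia
  dimnames(N) <- list(net$species, net$reactions$label)

  g <- igraph::graph_from_edgelist(
    cbind(net$reactions$from, net$reactions$to), directed = TRUE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  weak <- igraph::components(g, mode = "weak")$membership
  ell <- as.integer(max(weak))
  linkage_classes <- split(seq_len(n), weak)

  scc <- igraph::components(g, mode = "strong")$membership
  # terminal SCC: no edge leaves it in the condensation
  has_out <- tapply(scc[net$reactions$from] != scc[net$reactions$to],
                    scc[net$reactions$from], any)
  terminal <- setdiff(unique(scc),
                      as.integer(names(has_out))[unlist(has_out)])
  tslc <- lapply(sort(terminal), function(id) which(scc == id))
  t_count <- length(tslc)
  if (t_count > ell) {
    stop("network has t > ell (more terminal strong linkage classes than ",
         "linkage classes); such networks are considered in general to be ",
         "unsuited and are not supported")
  }

  s <- as.integer(numerical_rank(N))
  delta <- as.integer(n - ell - s)
  lambda <- as.integer(m - s)

  Lambda <- matrix(0, n, ell)
  for (j in seq_len(ell)) Lambda[linkage_classes[[j]], j] <- 1

  # B: left null space of Y A at generic positive rates; for t = l networks
  # this coincides with the left null space of N.  Two deterministic generic
  # rate draws guard against a non-generic accident.
  kg1 <- exp(sin(seq_len(r) * 1.7) + 0.5 * cos(seq_len(r)^2 * 0.31))
  kg2 <- exp(cos(seq_len(r) * 2.3) + 0.5 * sin(seq_len(r) * 0.77) + 0.2)
  B1 <- null_space(t(Y %*% (Ia %*% diag(kg1, r) %*% t(ia_source(net, n, r)))))
  B2 <- null_space(t(Y %*% (Ia %*% diag(kg2, r) %*% t(ia_source(net, n, r)))))
  if (ncol(B1) != ncol(B2) ||
      (ncol(B1) > 0 && numerical_rank(cbind(B1, B2)) != ncol(B1))) {
    stop("left null space of YA depends on the generic rate draw")
  }
  B <- nice_basis(B1)
  if (ncol(B) != m - s) stop("conservation-law count disagrees with m - s")
  rownames(B) <- net$species

  omega <- nice_basis(null_space(rbind(Y, t(Lambda))))
  if (ncol(omega) != delta) {
    stop("deficiency-subspace dimension disagrees with n - ell - s")
  }
  # order deficiency basis vectors by their first nonzero coordinate
  if (ncol(omega) > 1L) {
    lead <- apply(omega, 2, function(v) which(abs(v) > 1e-9)[1])
    omega <- omega[, order(lead), drop = FALSE]
  }

  laws <- vapply(seq_len(ncol(B)), function(j) {
    v <- B[, j]
    nz <- which(abs(v) > 1e-9)
    paste(ifelse(abs(v[nz] - 1) < 1e-9, net$species[nz],
                 sprintf("%g %s", v[nz], net$species[nz])), collapse = " + ")
  }, "")

  structure(list(network = net, Y = Y, incidence = Ia, N = N,
                 Lambda = Lambda, linkage_classes = linkage_classes,
                 terminal_strong_linkage_classes = tslc,
                 m = as.integer(m), n = as.integer(n), r = as.integer(r),
                 ell = ell, t = as.integer(t_count), s = s,
                 delta = delta, lambda = lambda,
                 B = B, omega = omega, conservation_laws = laws),
            class = "structural_summary")
}

# source-complex indicator matrix (n x r): column i is e_{from(i)}
#' @noRd
ia_source <- function(net, n, r) {
  S <- matrix(0, n, r)
  for (i in seq_len(r)) S[net$reactions$from[i], i] <- 1
  S
}

#' @export
print.structural_summary <- function(x, ...) {
  cat("CRNT structural summary\n")
  cat(sprintf("  species m = %d, complexes n = %d, reactions r = %d\n",
              x$m, x$n, x$r))
  cat(sprintf("  linkage classes l = %d, terminal strong l.c. t = %d\n",
              x$ell, x$t))
  cat(sprintf("  stoichiometric subspace dim s = %d\n", x$s))
  cat(sprintf("  deficiency delta = n - l - s = %d\n", x$delta))
  cat(sprintf("  manifold dimension lambda = m - s = %d\n", x$lambda))
  if (length(x$conservation_laws)) {
    cat("  conservation laws:\n")
    for (law in x$conservation_laws) cat("    ", law, "\n")
  }
  invisible(x)
}

#' Export the structural report as a JSON string
#' @param summary a `structural_summary`.
#' @export
structural_report_json <- function(summary) {
  as.character(jsonlite::toJSON(list(
    m = summary$m, n = summary$n, r = summary$r,
    linkage_classes = summary$ell, terminal_strong = summary$t,
    s = summary$s, deficiency = summary$delta, lambda = summary$lambda,
    conservation_laws = summary$conservation_laws,
    B = summary$B, omega = summary$omega
  ), auto_unbox = TRUE, digits = NA, pretty = TRUE))
}
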
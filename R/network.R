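#' Construct a mass-action reaction network
#'
#' A reaction network is described by the graph of its complexes: the nodes
#' are the complexes (formal non-negative integer combinations of species,
#' including the empty "zero" complex that stands for the environment) and
#' the directed edges are the reactions, each labelled with a rate-constant
#' name.  This representation is the single source of truth from which all
#' structural matrices of Chemical Reaction Network Theory are derived.
#'
#' @param species character vector of species identifiers (ordered).
#' @param complexes list of named numeric vectors; each element maps species
#'   names to positive integer molecularities.  An empty (length-zero) vector
#'   denotes the zero complex.
#' @param reactions data frame with columns `from`, `to` (1-based complex
#'   indices) and `label` (rate-constant name), one row per directed reaction.
#' @param rate_values named numeric vector of rate-constant values; may cover
#'   only a subset of the labels (the rest stay unset until estimation).
#'
#' @return An object of class `reaction_network`.
#' @examples
#' net <- parse_network_text("A <-> B ; k1_2, k2_1")
#' net
#' @export
reaction_network <- function(species, complexes, reactions,
                             rate_values = numeric(0)) {
  species <- as.character(species)
  if (anyDuplicated(species)) stop("duplicated species names")
  complexes <- lapply(complexes, function(cx) {
    if (length(cx) == 0L) return(numeric(0))
    cx <- unlist(cx)
    storage.mode(cx) <- "double"
    cx[order(match(names(cx), species))]
  })
  keys <- vapply(complexes, complex_key, "")
  if (anyDuplicated(keys)) {
    stop("duplicated complex: ", keys[duplicated(keys)][1])
  }
  for (cx in complexes) {
    bad <- setdiff(names(cx), species)
    if (length(bad)) stop("unknown species in a complex: ", bad[1])
    if (any(cx <= 0) || any(cx != round(cx))) {
      stop("molecularities must be positive integers")
    }
  }
  used <- unique(unlist(lapply(complexes, names)))
  orphan <- setdiff(species, used)
  if (length(orphan)) stop("species appears in no complex: ", orphan[1])
  reactions <- as.data.frame(reactions)
  reactions$from <- as.integer(reactions$from)
  reactions$to <- as.integer(reactions$to)
  reactions$label <- as.character(reactions$label)
  n <- length(complexes)
  if (any(reactions$from < 1L | reactions$from > n) ||
      any(reactions$to < 1L | reactions$to > n)) {
    stop("reaction refers to an invalid complex index")
  }
  if (any(reactions$from == reactions$to)) stop("self-loop reaction")
  if (anyDuplicated(reactions$label)) stop("duplicated rate-constant label")
  rate_values <- unlist(rate_values) %||% numeric(0)
  if (length(rate_values)) {
    bad <- setdiff(names(rate_values), reactions$label)
    if (length(bad)) stop("rate value for unknown label: ", bad[1])
    if (any(!is.na(rate_values) & rate_values <= 0)) {
      stop("nonpositive rate value for label: ",
           names(rate_values)[!is.na(rate_values) & rate_values <= 0][1])
    }
  }
  structure(list(species = species, complexes = complexes,
                 reactions = reactions,
                 rate_values = rate_values[!is.na(rate_values)]),
            class = "reaction_network")
}

#' @noRd
complex_key <- function(cx) {
  if (length(cx) == 0L) return("0")
  paste(sprintf("%g*%s", cx, names(cx)), collapse = "+")
}

#' Human-readable complex label, e.g. `"E + S"` or `"0"`.
#' @param net a `reaction_network`.
#' @param j complex index.
#' @export
complex_label <- function(net, j) {
  cx <- net$complexes[[j]]
  if (length(cx) == 0L) return("0")
  paste(ifelse(cx == 1, names(cx), sprintf("%g %s", cx, names(cx))),
        collapse = " + ")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Mass-action reaction network: %d species, %d complexes, %d reactions\n",
              length(x$species), length(x$complexes), nrow(x$reactions)))
  cat("species:", paste(x$species, collapse = ", "), "\n")
  for (i in seq_len(nrow(x$reactions))) {
    r <- x$reactions[i, ]
    v <- if (r$label %in% names(x$rate_values)) {
      sprintf(" = %g", x$rate_values[[r$label]])
    } else ""
    cat(sprintf("  %s -> %s ; %s%s\n", complex_label(x, r$from),
                complex_label(x, r$to), r$label, v))
  }
  invisible(x)
}

#' Parse a network from its JSON description
#'
#' The schema is
#' `{"species":[...], "complexes":[{"S":1,"E":1}, {}, ...],`
#' `"reactions":[{"from":1,"to":4,"k":"k1_4","value":1.0}, ...]}`
#' with 1-based complex indices and `{}` denoting the zero complex.
#' `value` entries are optional.  Documents written by [write_network()]
#' round-trip bit-identically.
#'
#' @param path path to a JSON file, or a literal JSON string.
#' @return a [reaction_network()].
#' @export
parse_network <- function(path) {
  txt <- if (length(path) == 1L && file.exists(path)) {
    paste(readLines(path, warn = FALSE), collapse = "\n")
  } else paste(path, collapse = "\n")
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  for (f in c("species", "complexes", "reactions")) {
    if (is.null(doc[[f]])) stop("network document lacks field: ", f)
  }
  species <- unlist(doc$species)
  complexes <- lapply(doc$complexes, function(cx) unlist(cx) %||% numeric(0))
  reactions <- do.call(rbind, lapply(doc$reactions, function(r) {
    data.frame(from = r$from, to = r$to, label = r$k,
               stringsAsFactors = FALSE)
  }))
  vals <- unlist(lapply(doc$reactions, function(r) {
    if (is.null(r$value)) return(NULL)
    stats::setNames(as.numeric(r$value), r$k)
  }))
  reaction_network(species, complexes, reactions, vals %||% numeric(0))
}

#' Parse the one-reaction-per-line text dialect
#'
#' Each line reads `"E + S -> ES ; k1_4"`;  `"<->"` expands to the two
#' directed reactions and takes two comma-separated labels.  Complexes are
#' numbered in order of first appearance;  `0` denotes the zero complex.
#'
#' @param lines character vector of reaction lines (or one string with
#'   embedded newlines).
#' @param rate_values optional named numeric vector of rate values.
#' @export
parse_network_text <- function(lines, rate_values = numeric(0)) {
  lines <- unlist(strsplit(lines, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  complexes <- list(); keys <- character(0)
  species <- character(0)
  parse_cx <- function(s) {
    s <- trimws(s)
    if (s == "0") return(numeric(0))
    parts <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    cx <- numeric(0)
    for (p in parts) {
      mm <- regmatches(p, regexec("^([0-9]*)\\s*([A-Za-z_][A-Za-z0-9_]*)$", p))[[1]]
      if (length(mm) == 0L) stop("cannot parse complex term: ", p)
      mult <- if (nzchar(mm[2])) as.numeric(mm[2]) else 1
      cx[mm[3]] <- (cx[mm[3]] %||% 0) + mult
      if (is.na(cx[mm[3]])) cx[mm[3]] <- mult
    }
    cx[is.na(cx)] <- 1
    cx
  }
  cx_index <- function(cx) {
    key <- complex_key(cx)
    i <- match(key, keys)
    if (!is.na(i)) return(i)
    complexes[[length(complexes) + 1L]] <<- cx
    keys <<- c(keys, key)
    species <<- union(species, names(cx))
    length(complexes)
  }
  rows <- list()
  for (ln in lines) {
    halves <- strsplit(ln, ";", fixed = TRUE)[[1]]
    if (length(halves) != 2L) stop("line lacks '; label' part: ", ln)
    labels <- trimws(strsplit(halves[2], ",", fixed = TRUE)[[1]])
    rev2 <- grepl("<->", halves[1], fixed = TRUE)
    arrow <- if (rev2) "<->" else "->"
    sides <- trimws(strsplit(halves[1], arrow, fixed = TRUE)[[1]])
    if (length(sides) != 2L) stop("cannot parse reaction: ", ln)
    i <- cx_index(parse_cx(sides[1])); j <- cx_index(parse_cx(sides[2]))
    if (rev2) {
      if (length(labels) != 2L) stop("'<->' needs two labels: ", ln)
      rows[[length(rows) + 1L]] <- data.frame(from = i, to = j, label = labels[1])
      rows[[length(rows) + 1L]] <- data.frame(from = j, to = i, label = labels[2])
    } else {
      if (length(labels) != 1L) stop("'->' needs one label: ", ln)
      rows[[length(rows) + 1L]] <- data.frame(from = i, to = j, label = labels)
    }
  }
  reaction_network(species, complexes, do.call(rbind, rows), rate_values)
}

#' Serialize a network to the JSON schema read by [parse_network()]
#'
#' @param net a `reaction_network`.
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @export
write_network <- function(net, path = NULL) {
  doc <- list(
    species = net$species,
    complexes = lapply(net$complexes, function(cx) {
      if (length(cx) == 0L) return(stats::setNames(list(), character(0)))
      as.list(cx)
    }),
    reactions = lapply(seq_len(nrow(net$reactions)), function(i) {
      r <- net$reactions[i, ]
      out <- list(from = r$from, to = r$to, k = r$label)
      if (r$label %in% names(net$rate_values)) {
        out$value <- net$rate_values[[r$label]]
      }
      out
    })
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(path)
}

#' Set rate-constant values on a network
#'
#' @param net a `reaction_network`.
#' @param k named numeric vector of strictly positive values.
#' @return the network with `rate_values` updated.
#' @export
set_rates <- function(net, k) {
  k <- unlist(k)
  bad <- setdiff(names(k), net$reactions$label)
  if (length(bad)) stop("unknown rate label: ", bad[1])
  if (any(k <= 0)) stop("rate values must be strictly positive")
  net$rate_values[names(k)] <- k
  net
}

#' Full rate vector in reaction order
#'
#' @param net a `reaction_network`.
#' @param k optional named vector overriding / completing `net$rate_values`.
#' @return numeric vector of length `r`, named by label.
#' @export
rate_vector <- function(net, k = NULL) {
  # fast path: a full-length unnamed numeric vector is taken as already
  # resolved in reaction order
  if (is.numeric(k) && is.null(names(k)) &&
      length(k) == nrow(net$reactions)) {
    return(stats::setNames(as.numeric(k), net$reactions$label))
  }
  vals <- net$rate_values
  if (!is.null(k)) vals[names(k)] <- k
  miss <- setdiff(net$reactions$label, names(vals))
  if (length(miss)) stop("unset rate value: ", paste(miss, collapse = ", "))
  out <- vals[net$reactions$label]
  if (any(out <= 0)) stop("nonpositive rate value")
  stats::setNames(as.numeric(out), net$reactions$label)
}
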
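#' Read an observation set from CSV plus a JSON configuration
#'
#' The CSV has columns `observable_name`, `point` (`l`/`u`), `value`,
#' `replicate_id`; single-replicate rows define the noise-free observables
#' (values are averaged per observable and point when several replicates
#' are present, and the full table is attached as replicates).  The JSON
#' configuration carries the stimulus block and the observable map:
#' \preformatted{
#' {"stimulus": {"kind": "conservation", "index": 1,
#'               "values": [0.007079, 0.010973]},
#'  "Q": {"S": {"S": 1}, "ESS": {"ESS": 1}, "P": {"P": 1}}}
#' }
#' (for a rate stimulus: `"kind": "rate", "label": "k7_13", "b": [...]`).
#'
#' @param csv_path observations CSV path.
#' @param config_path JSON configuration path (or JSON string).
#' @param species species ordering of the network (for assembling Q).
#' @return an [observation_set()].
#' @export
read_observations_csv <- function(csv_path, config_path, species) {
  tab <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("observable_name", "point", "value")
  if (!all(need %in% names(tab))) {
    stop("observations CSV needs columns: ", paste(need, collapse = ", "))
  }
  cfg_txt <- if (file.exists(config_path)) {
    paste(readLines(config_path, warn = FALSE), collapse = "\n")
  } else config_path
  cfg <- jsonlite::fromJSON(cfg_txt, simplifyVector = FALSE)
  st <- lapply(cfg$stimulus, unlist)
  st$values <- as.numeric(st$values)
  if (!is.null(st$b)) st$b <- as.numeric(st$b)
  if (!is.null(st$b_other)) st$b_other <- as.numeric(st$b_other)
  if (!is.null(st$index)) st$index <- as.integer(st$index)
  obs_names <- names(cfg$Q)
  Q <- t(vapply(cfg$Q, function(row) {
    v <- stats::setNames(rep(0, length(species)), species)
    row <- unlist(row)
    v[names(row)] <- row
    v
  }, stats::setNames(numeric(length(species)), species)))
  rownames(Q) <- obs_names
  q <- matrix(NA_real_, 2, length(obs_names),
              dimnames = list(c("l", "u"), obs_names))
  for (point in c("l", "u")) for (nm in obs_names) {
    sel <- tab$point == point & tab$observable_name == nm
    if (!any(sel)) stop(sprintf("no observation for %s at point %s", nm, point))
    q[point, nm] <- mean(tab$value[sel])
  }
  reps <- NULL
  if ("replicate_id" %in% names(tab) &&
      any(duplicated(tab[, c("observable_name", "point")]))) {
    reps <- data.frame(point = tab$point, observable = tab$observable_name,
                       replicate = tab$replicate_id, value = tab$value)
  }
  observation_set(stimulus = st, Q = Q, q = q, replicates = reps)
}

#' Write a replicate table as an observations CSV
#'
#' @param table a `replicate_table`.
#' @param path output CSV path.
#' @export
write_observations_csv <- function(table, path) {
  utils::write.csv(
    data.frame(observable_name = table$observable, point = table$point,
               value = table$value, replicate_id = table$replicate),
    path, row.names = FALSE)
  invisible(path)
}

#' Serialize an estimate (or other result) to JSON with provenance
#'
#' Every artifact embeds the package version, a hash of the resolved
#' configuration and the seeds used, so runs can be reproduced exactly.
#'
#' @param result a `bif_estimate`, `mc_result` or plain list.
#' @param path output path (or `NULL` for the JSON string).
#' @param config resolved configuration list to hash and embed.
#' @param seeds named list/vector of seeds.
#' @export
write_result_json <- function(result, path = NULL, config = list(),
                              seeds = list()) {
  if (inherits(result, "bif_estimate")) {
    result <- list(k = as.list(result$k), alpha_l = result$alpha_l,
                   alpha_u = result$alpha_u, c_l = as.list(result$c_l),
                   c_u = as.list(result$c_u), J0 = result$J0, J1 = result$J1,
                   J2 = result$J2, feasibility = result$feasibility,
                   converged = result$converged)
  } else if (inherits(result, "mc_result")) {
    result <- list(M = result$M, failed = result$failed, level = result$level,
                   ci = apply(result$ci, 2, as.list),
                   correlation = result$correlation)
  }
  payload <- list(
    tool = "invbif",
    version = as.character(utils::packageVersion("invbif")),
    config_hash = config_hash(config),
    seeds = seeds,
    result = result)
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                          pretty = TRUE, null = "null")
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(path)
}

# small deterministic hash (djb2 over the serialized config)
#' @noRd
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (v in utf8ToInt(as.character(s))) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", h)
}
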
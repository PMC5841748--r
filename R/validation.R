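#' Per-node direction of change between two conditions
#'
#' Compares mean attractor activation between a disease and a reference
#' (healthy) simulation node by node. A node is `up` if the disease mean
#' exceeds the healthy mean by more than `tolerance`, `down` if it is lower
#' by more than `tolerance`, otherwise `equal`. The default tolerance of
#' 0.02 absolute activation absorbs Monte-Carlo noise at the reference
#' protocol (25 repetitions x 5000 iterations).
#'
#' @param healthy,disease [summarize_activation()] results over the same
#'   node set.
#' @param tolerance Non-negative activation difference treated as no change.
#' @return A `direction_report` data.frame with columns `node`, `healthy`,
#'   `disease`, `difference`, `direction`.
#' @export
compare_conditions <- function(healthy, disease, tolerance = 0.02) {
  stopifnot(inherits(healthy, "activation_summary"),
            inherits(disease, "activation_summary"), tolerance >= 0)
  if (!identical(names(healthy$mean), names(disease$mean)))
    stop("the two summaries cover different node sets", call. = FALSE)
  diff <- disease$mean - healthy$mean
  out <- data.frame(node = names(diff),
                    healthy = unname(healthy$mean),
                    disease = unname(disease$mean),
                    difference = unname(diff),
                    direction = ifelse(diff > tolerance, "up",
                                       ifelse(diff < -tolerance, "down", "equal")),
                    stringsAsFactors = FALSE)
  attr(out, "tolerance") <- tolerance
  class(out) <- c("direction_report", "data.frame")
  out
}

#' Concordance of simulated directions with literature annotations
#'
#' Scores each annotated node's simulated disease-vs-healthy direction
#' against its literature status. The headline count is
#' `matched_upregulated`: nodes annotated Upregulated whose simulated
#' direction is up. Nodes annotated Altered or Unknown carry no expected
#' direction; their simulated behaviour is tallied separately
#' (`altered_up`, `unknown_up`). Mismatches are the annotated-Upregulated
#' nodes whose simulated direction is not up.
#'
#' @param directions A [compare_conditions()] report.
#' @param annotations A data.frame like [literature_annotations()] with
#'   columns `node` and `status`, one row per node of the report.
#' @return A `concordance_report`: list with `counts` (named integer
#'   vector), `mismatches` (character vector of node names) and `table`
#'   (per-node merge of direction and status).
#' @export
concordance <- function(directions, annotations = literature_annotations()) {
  stopifnot(all(c("node", "status") %in% names(annotations)))
  missing <- setdiff(directions$node, annotations$node)
  if (length(missing))
    stop("missing annotation for node(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab <- merge(directions, annotations[, c("node", "status")],
               by = "node", sort = TRUE)
  up <- tab$direction == "up"
  counts <- c(matched_upregulated = sum(tab$status == "Upregulated" & up),
              altered_up = sum(tab$status == "Altered" & up),
              unknown_up = sum(tab$status == "Unknown" & up),
              mismatches = sum(tab$status == "Upregulated" & !up))
  structure(list(counts = counts,
                 mismatches = tab$node[tab$status == "Upregulated" & !up],
                 table = tab),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>\n")
  print(x$counts)
  if (length(x$mismatches))
    cat("mismatched upregulated nodes:",
        paste(x$mismatches, collapse = ", "), "\n")
  invisible(x)
}

#' Run the healthy-versus-disease validation of the bundled model
#'
#' Simulates the bundled network under the healthy and IBD condition presets
#' with an identical configuration, compares per-node attractor activation,
#' and scores the directions against the literature annotations.
#'
#' @param config_args List of arguments passed to [ibd_sim_config()] for
#'   both runs (e.g. `list(iterations = 5000, repetitions = 25, seed = 1)`).
#' @param tolerance Passed to [compare_conditions()].
#' @return A list with `healthy`, `disease` (activation summaries),
#'   `directions` and `concordance`.
#' @export
validate_ibd_model <- function(config_args = list(), tolerance = 0.02) {
  run <- function(label) {
    cond <- ibd_condition(label)
    cfg <- do.call(ibd_sim_config, c(list(condition = cond), config_args))
    summarize_activation(simulate_network(build_ibd_model(cond), cfg))
  }
  healthy <- run("healthy")
  disease <- run("IBD")
  directions <- compare_conditions(healthy, disease, tolerance)
  list(healthy = healthy, disease = disease, directions = directions,
       concordance = concordance(directions))
}

#' Paired bar chart of healthy versus disease activation
#'
#' @param directions A [compare_conditions()] report.
#' @param file Image path (`.pdf` or `.png`).
#' @return The path, invisibly.
#' @export
plot_conditions <- function(directions, file = "conditions.pdf") {
  if (grepl("\\.png$", file)) grDevices::png(file, 1800, 900, res = 160)
  else grDevices::pdf(file, width = 11, height = 5)
  op <- graphics::par(mar = c(8, 4, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  m <- t(as.matrix(directions[, c("healthy", "disease")]))
  colnames(m) <- directions$node
  graphics::barplot(m, beside = TRUE, las = 2, col = c("grey70", "#B2182B"),
                    ylab = "mean activation", ylim = c(0, 1.15),
                    cex.names = 0.6)
  graphics::legend("topright", c("healthy", "IBD"),
                   fill = c("grey70", "#B2182B"), bty = "n")
  invisible(file)
}
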
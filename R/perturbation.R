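#' Single-node knockout screen: the Perturbation Index matrix
#'
#' Clamps each node to 0 in turn, re-runs the simulation with the same
#' configuration and seed policy as an unperturbed baseline, and reports the
#' Perturbation Index PI(k, j) = activation ratio of observed node `j` under
#' knockout of `k` versus baseline. To keep the ratio defined and bounded
#' when a baseline mean is 0, both means are shifted by
#' epsilon = 1/(iterations * repetitions) — one ON state in the whole
#' ensemble — so PI is exactly 1 when both means are 0. The reference screen
#' protocol is 24 repetitions over 999 iterations, asynchronous.
#'
#' @param model A `network_model`.
#' @param config A [sim_config()]; `config$perturbations` must be empty (the
#'   screen owns the clamps). For the bundled model use [ibd_sim_config()]
#'   so antigens start ON.
#' @param nodes Nodes to knock out (default: all).
#' @return A `perturbation_matrix`: list with `PI` (knocked-out x observed
#'   matrix), `baseline` (the unperturbed [summarize_activation()] result),
#'   `epsilon` and `config`.
#' @export
knockout_matrix <- function(model,
                            config = sim_config(iterations = 999L,
                                                repetitions = 24L),
                            nodes = model_nodes(model)) {
  validate_model(model)
  if (length(config$perturbations))
    stop("config must not carry perturbations; the screen sets its own clamps",
         call. = FALSE)
  stopifnot(all(nodes %in% model_nodes(model)))
  baseline <- summarize_activation(simulate_network(model, config))
  eps <- 1 / (config$iterations * config$repetitions)
  PI <- matrix(NA_real_, length(nodes), length(model_nodes(model)),
               dimnames = list(knocked_out = nodes,
                               observed = model_nodes(model)))
  for (k in nodes) {
    cfg <- config
    cfg$perturbations <- stats::setNames("knockout", k)
    m <- summarize_activation(simulate_network(model, cfg))$mean
    PI[k, ] <- (m + eps) / (baseline$mean + eps)
  }
  structure(list(PI = PI, baseline = baseline, epsilon = eps,
                 config = config),
            class = "perturbation_matrix")
}

#' @export
print.perturbation_matrix <- function(x, ...) {
  cat(sprintf("<perturbation_matrix> %d knockouts x %d observed nodes\n",
              nrow(x$PI), ncol(x$PI)))
  invisible(x)
}

#' Classify Perturbation Index values
#'
#' PI <= `low` is `downregulated`, PI >= `high` is `overexpressed`,
#' strictly between the thresholds is `unchanged`. Boundaries are closed on
#' the altered side ("0.8 or smaller" / "1.25 or greater").
#'
#' @param x A `perturbation_matrix` or a numeric matrix/vector of PI values.
#' @param low,high Classification thresholds (defaults 0.8 and 1.25).
#' @return A `pi_classification`: list with `labels` (character matrix) and
#'   `thresholds`.
#' @export
classify_pi <- function(x, low = 0.8, high = 1.25) {
  stopifnot(low < high)
  PI <- if (inherits(x, "perturbation_matrix")) x$PI else x
  labels <- ifelse(PI <= low, "downregulated",
                   ifelse(PI >= high, "overexpressed", "unchanged"))
  structure(list(labels = labels, thresholds = c(low = low, high = high)),
            class = "pi_classification")
}

#' Hierarchical clustering of a perturbation screen
#'
#' Agglomerative clustering (average linkage on Euclidean distance) of the
#' knockout profiles (rows of the PI matrix) and of the response profiles
#' (columns), so knockouts that cause similar alterations — and nodes that
#' respond alike — are adjacent in the rendered heatmap. Deterministic given
#' the matrix.
#'
#' @param x A `perturbation_matrix` or numeric matrix.
#' @param method Linkage passed to [stats::hclust()].
#' @return A `cluster_order`: list with `row_order`, `col_order` (leaf
#'   orders as names), `row_tree`, `col_tree` (hclust objects).
#' @export
cluster_order <- function(x, method = "average") {
  PI <- if (inherits(x, "perturbation_matrix")) x$PI else x
  row_tree <- stats::hclust(stats::dist(PI), method = method)
  col_tree <- stats::hclust(stats::dist(t(PI)), method = method)
  structure(list(row_order = rownames(PI)[row_tree$order],
                 col_order = colnames(PI)[col_tree$order],
                 row_tree = row_tree, col_tree = col_tree),
            class = "cluster_order")
}

#' Newick text for a clustering tree
#'
#' @param tree An `hclust` object (e.g. `cluster_order()$row_tree`).
#' @return Newick string.
#' @export
tree_newick <- function(tree) {
  ape::write.tree(ape::as.phylo(tree))
}

#' Render a perturbation screen as a clustered heatmap
#'
#' Colour follows the classification bands: blue for downregulated
#' (PI <= low), black for unchanged, orange for overexpressed
#' (PI >= high). The heatmap shows observed nodes as rows and knockouts as
#' columns with dendrograms from [cluster_order()]; the PI matrix is also
#' written as TSV next to the image.
#'
#' @param x A `perturbation_matrix`.
#' @param classification A [classify_pi()] result (for the thresholds).
#' @param order A [cluster_order()] result; computed if `NULL`.
#' @param file Image path (`.pdf` or `.png`).
#' @return Invisibly, the image path and the TSV path.
#' @export
render_heatmap <- function(x, classification = classify_pi(x),
                           order = cluster_order(x),
                           file = "perturbation_heatmap.pdf") {
  PI <- t(x$PI)  # rows: observed nodes; columns: knockouts
  thr <- classification$thresholds
  breaks <- c(0, seq(0, thr[["low"]], length.out = 24),
              thr[["high"]], max(2, max(PI), na.rm = TRUE) + 1e-9)
  breaks[1] <- -1e-9
  colours <- c(grDevices::colorRampPalette(c("#08306B", "#4292C6"))(24),
               "black", "#E08214")
  ph <- pheatmap::pheatmap(PI,
                           cluster_rows = order$col_tree,
                           cluster_cols = order$row_tree,
                           breaks = breaks, color = colours,
                           fontsize = 6, silent = TRUE)
  dev_fun <- if (grepl("\\.png$", file)) {
    function(f) grDevices::png(f, width = 2000, height = 1800, res = 200)
  } else function(f) grDevices::pdf(f, width = 10, height = 9)
  dev_fun(file)
  grid::grid.newpage()
  grid::grid.draw(ph$gtable)
  grDevices::dev.off()
  tsv <- sub("\\.(pdf|png)$", ".tsv", file)
  write_pi_matrix(x, tsv)
  invisible(list(image = file, tsv = tsv))
}

#' Write / read a PI matrix as TSV
#'
#' The TSV has the observed nodes as the first column and one column per
#' knocked-out node; `read_pi_matrix()` reconstructs the numeric matrix in
#' the orientation of `knockout_matrix()` (knockouts as rows).
#'
#' @param x A `perturbation_matrix`.
#' @param path TSV path.
#' @return `write_pi_matrix()`: the path, invisibly. `read_pi_matrix()`: a
#'   numeric matrix.
#' @export
write_pi_matrix <- function(x, path) {
  df <- data.frame(node = colnames(x$PI), t(x$PI), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pi_matrix
#' @export
read_pi_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$node
  names(dimnames(m)) <- c("observed", "knocked_out")
  t(m)
}
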
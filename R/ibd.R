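#' Condition presets for the bundled IBD model
#'
#' The disease condition models impaired antigen clearance: the antimicrobial
#' effectors must stay active for `Ag_elim = 6` consecutive iterations before
#' an antigen input switches off. The healthy condition keeps the identical
#' rule set and models effective clearance as `Ag_elim = 1` (a single
#' iteration of effector activity clears antigen), exposed here as a knob.
#' In both conditions the three bacterial antigens (PGN, LPS, MDP) start ON
#' and every other node starts OFF — chronic antigen exposure.
#'
#' @param label `"IBD"` or `"healthy"`.
#' @param ag_elim Optional integer overriding the condition's antigen
#'   elimination threshold.
#' @return An `ibd_condition` list with `label`, `overrides` (named integer
#'   vector of parameter overrides) and `initial_state`.
#' @export
ibd_condition <- function(label = c("IBD", "healthy"), ag_elim = NULL) {
  label <- match.arg(label)
  if (is.null(ag_elim)) ag_elim <- if (label == "IBD") 6L else 1L
  stopifnot(ag_elim >= 1L)
  structure(list(label = label,
                 overrides = c(Ag_elim = as.integer(ag_elim)),
                 initial_state = c(PGN = 1L, LPS = 1L, MDP = 1L)),
            class = "ibd_condition")
}

#' Build the bundled 43-node IBD network
#'
#' Loads the packaged model file (43 nodes: the three bacterial antigen
#' inputs PGN, LPS and MDP, 39 internal immune nodes and the MMPs
#' tissue-damage output) and applies the condition's parameter overrides.
#' Healthy and disease models differ only in parameters, never in rule
#' structure.
#'
#' @param condition An [ibd_condition()]; default the IBD preset.
#' @return A validated `network_model` with the condition recorded in
#'   `metadata$condition` and its initial state in `metadata$initial_state`.
#' @examples
#' m <- build_ibd_model()
#' length(model_nodes(m))
#' @export
build_ibd_model <- function(condition = ibd_condition("IBD")) {
  stopifnot(inherits(condition, "ibd_condition"))
  model <- read_model(system.file("extdata", "ibd_model.dsl",
                                  package = "ibdlogic", mustWork = TRUE))
  model$parameters[names(condition$overrides)] <- condition$overrides
  model$metadata$condition <- condition$label
  model$metadata$initial_state <- condition$initial_state
  validate_model(model)
}

#' Simulation configuration for an IBD-model condition
#'
#' Convenience wrapper around [sim_config()] that installs the condition's
#' chronic-exposure initial state (antigens ON).
#'
#' @param condition An [ibd_condition()].
#' @param ... Passed to [sim_config()].
#' @return A `sim_config`.
#' @export
ibd_sim_config <- function(condition = ibd_condition("IBD"), ...) {
  sim_config(..., initial_state = condition$initial_state)
}

#' Therapy presets
#'
#' The seven simulated therapies: five clinical antibodies modelled as
#' knockout of their target cytokine, granulocyte/monocyte apheresis (GMA)
#' as knockout of the macrophage node, and recombinant human IL10 as IL10
#' overexpression (clamp to 1).
#'
#' @return Named list of `therapy_preset` objects, each with `name` and
#'   `perturbations` (named character vector, node -> mode).
#' @export
therapy_presets <- function() {
  preset <- function(name, perturbations)
    structure(list(name = name, perturbations = perturbations),
              class = "therapy_preset")
  list(
    `anti-TNFa`      = preset("anti-TNFa",      c(TNFa = "knockout")),
    `GMA`            = preset("GMA",            c(MACR = "knockout")),
    `anti-IL17`      = preset("anti-IL17",      c(IL17 = "knockout")),
    `rhuIL-10`       = preset("rhuIL-10",       c(IL10 = "overexpress")),
    `anti-IFNg`      = preset("anti-IFNg",      c(IFNg = "knockout")),
    `anti-IL2`       = preset("anti-IL2",       c(IL2 = "knockout")),
    `anti-IL12-IL23` = preset("anti-IL12-IL23", c(IL12 = "knockout",
                                                  IL23 = "knockout"))
  )
}

#' Literature annotations of node expression in IBD patients
#'
#' The transcription of the published per-node expression survey: 31 nodes
#' reported upregulated in patients, 9 altered (conflicting or inconclusive
#' reports) and 3 unknown. The regulatory T cell and dendritic cell nodes
#' are reported downregulated in blood but upregulated in the mucosa; since
#' the model represents the mucosal compartment they are scored as
#' upregulated, with the mixed-compartment text kept in `note`.
#'
#' @return A data.frame with columns `node`, `status` (`Upregulated`,
#'   `Altered`, `Unknown`) and `note`.
#' @export
literature_annotations <- function() {
  path <- system.file("extdata", "table3_annotations.tsv",
                      package = "ibdlogic", mustWork = TRUE)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
                           na.strings = NULL)
  ann$note[is.na(ann$note)] <- ""
  ann
}
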
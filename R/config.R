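# Toolkit configuration: every numeric constant of the pipeline in one place,
# serializable to/from YAML so CLI runs are reproducible.

#' Toolkit configuration
#'
#' @param allele_fraction_cutoff tumor-DNA allele fraction below which a
#'   variant with no RNA ALT evidence is treated as a likely artifact
#'   (default 0.1, compared strictly).
#' @param max_caller_reject maximum number of caller rejections tolerated by
#'   the consensus filter (default 2).
#' @param expression_threshold gene expression at or below which a gene is
#'   treated as unexpressed (default 0).
#' @param percentile_cutoff percentile-rank cutoff for binders; calls with a
#'   rank strictly greater than this are dropped (default 5).
#' @param overlap_rank_window maximum percentile difference for a 9-mer and a
#'   10-mer on the same allele to count as "similar affinity" (default 2).
#' @param iar_weights length-4 non-negative weights for the composite
#'   ImmunoActive-Region score: best-binder affinity, expression, promiscuity,
#'   9/10-mer overlap count.
#' @param groove_cutoff distance in Angstrom defining the binding groove:
#'   heavy-chain residues with any atom within this distance of any peptide
#'   atom (default 3.5).
#' @param n_models number of independently repacked models per allele
#'   (default 100).
#' @param top_k number of lowest-energy models averaged into the reported
#'   binding energy (default 10); must not exceed `n_models`.
#' @param sasa_probe solvent probe radius in Angstrom (default 1.4).
#' @param sasa_points number of sphere sample points per atom (default 960).
#' @param peptide_lengths epitope lengths to window (default 9, 10, 15).
#' @param master_seed master seed from which all stochastic steps derive
#'   their substreams.
#' @return a list of class `tool_config`.
#' @export
tool_config <- function(allele_fraction_cutoff = 0.1,
                        max_caller_reject = 2L,
                        expression_threshold = 0,
                        percentile_cutoff = 5.0,
                        overlap_rank_window = 2.0,
                        iar_weights = c(0.4, 0.3, 0.2, 0.1),
                        groove_cutoff = 3.5,
                        n_models = 100L,
                        top_k = 10L,
                        sasa_probe = 1.4,
                        sasa_points = 960L,
                        peptide_lengths = c(9L, 10L, 15L),
                        master_seed = 20260929L) {
  cfg <- list(allele_fraction_cutoff = allele_fraction_cutoff,
              max_caller_reject = as.integer(max_caller_reject),
              expression_threshold = expression_threshold,
              percentile_cutoff = percentile_cutoff,
              overlap_rank_window = overlap_rank_window,
              iar_weights = iar_weights,
              groove_cutoff = groove_cutoff,
              n_models = as.integer(n_models),
              top_k = as.integer(top_k),
              sasa_probe = sasa_probe,
              sasa_points = as.integer(sasa_points),
              peptide_lengths = as.integer(peptide_lengths),
              master_seed = as.integer(master_seed))
  validate_config(cfg)
  class(cfg) <- c("tool_config", "list")
  cfg
}

#' @keywords internal
validate_config <- function(cfg) {
  pos <- c("allele_fraction_cutoff", "percentile_cutoff", "groove_cutoff",
           "sasa_probe")
  for (k in pos)
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) stop(k, " must be > 0")
  if (cfg$top_k > cfg$n_models) stop("top_k must be <= n_models")
  if (length(cfg$iar_weights) != 4 || any(cfg$iar_weights < 0))
    stop("iar_weights must be 4 non-negative numbers")
  if (any(cfg$peptide_lengths < 8))
    stop("peptide_lengths must be >= 8")
  invisible(TRUE)
}

#' Read a tool_config from YAML
#' @param path YAML file; keys matching [tool_config()] arguments override
#'   the defaults.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(tool_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(tool_config, vals)
}

#' Write a tool_config to YAML
#' @param cfg a `tool_config`.
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
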
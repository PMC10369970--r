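#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy an expert ensemble into member coefficients
#'
#' @param x An `expert_ensemble`.
#' @param ... Unused.
#' @return Tibble with `member`, `term`, `estimate`.
#' @export
tidy.expert_ensemble <- function(x, ...) {
  tibble::tibble(
    member = rep(seq_len(ncol(x$coefs)), each = nrow(x$coefs)),
    term = rep(rownames(x$coefs), times = ncol(x$coefs)),
    estimate = as.vector(x$coefs)
  )
}

#' One-row summary of an expert ensemble
#'
#' @param x An `expert_ensemble`.
#' @param ... Unused.
#' @return Tibble with dataset, ensemble size, feature count, regularization
#'   and convergence summary.
#' @export
glance.expert_ensemble <- function(x, ...) {
  tibble::tibble(
    dataset_id = x$dataset_id, cell_type = x$cell_type,
    n_models = x$n_models, n_features = length(x$feature_names),
    C = x$C, weighted_activating_share = x$weights$weighted_activating_share,
    n_converged = sum(x$converged)
  )
}

#' Tidy an HMM into long emission parameters
#'
#' @param x An `hmm_model`.
#' @param ... Unused.
#' @return Tibble with `state`, `track`, `emission`.
#' @export
tidy.hmm_model <- function(x, ...) {
  tibble::tibble(
    state = rep(seq_len(x$K), times = x$M),
    track = rep(x$track_names, each = x$K),
    emission = as.vector(x$E)
  )
}

#' One-row summary of an HMM
#'
#' @param x An `hmm_model`.
#' @param ... Unused.
#' @return Tibble with `K`, `M`, mean self-transition probability and final
#'   training log-likelihood when available.
#' @export
glance.hmm_model <- function(x, ...) {
  ll <- attr(x, "loglik")
  tibble::tibble(
    K = x$K, M = x$M,
    mean_self_transition = mean(diag(x$A)),
    log_likelihood = if (is.null(ll)) NA_real_ else ll[length(ll)]
  )
}

#' Summarize an evaluation across repetitions
#'
#' @param x An `expert_evaluation` tibble.
#' @param ... Unused.
#' @return One row per dataset and scheme with median/mean AUROC.
#' @export
glance.expert_evaluation <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x, .data$dataset_id, .data$scheme),
    n_repetitions = dplyr::n(),
    median_auroc = stats::median(.data$auroc),
    mean_auroc = mean(.data$auroc),
    sd_auroc = stats::sd(.data$auroc),
    .groups = "drop"
  )
}

#' Emission heatmap of a fitted HMM
#'
#' @param object An `hmm_model`.
#' @param ... Unused.
#' @return A ggplot: states x tracks tile plot of emission probabilities.
#' @export
autoplot.hmm_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$track,
                                   y = factor(.data$state,
                                              levels = rev(seq_len(object$K))),
                                   fill = .data$emission)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_gradient(low = "white", high = "#08519c",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "expert track", y = "state",
                  fill = "emission\nprobability") +
    ggplot2::theme_minimal()
}

#' AUROC distribution plot for an evaluation
#'
#' @param object An `expert_evaluation` tibble.
#' @param ... Unused.
#' @return A ggplot of per-repetition AUROCs by dataset.
#' @export
autoplot.expert_evaluation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dataset_id,
                                       y = .data$auroc)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "held-out AUROC") +
    ggplot2::theme_minimal()
}

#' State-frequency profile around TSSs
#'
#' @param object A `tss_profile` tibble.
#' @param ... Unused.
#' @return A ggplot of per-offset state frequencies (or mean score).
#' @export
autoplot.tss_profile <- function(object, ...) {
  if ("freq" %in% names(object)) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$offset, y = .data$freq,
                                         color = .data$state_name)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "offset from TSS (bp)", y = "state frequency",
                    color = "state") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$offset,
                                         y = .data$mean_score)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "offset from TSS (bp)", y = "mean score") +
      ggplot2::theme_minimal()
  }
}

#' Fold-enrichment bar plot
#'
#' @param object An `enrichment_table` tibble.
#' @param ... Unused.
#' @return A ggplot of per-state fold enrichments.
#' @export
autoplot.enrichment_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$state),
                                       y = .data$fold)) +
    ggplot2::geom_col(fill = "#3182bd") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$annotation)) +
    ggplot2::labs(x = "state", y = "fold enrichment") +
    ggplot2::theme_minimal()
}
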
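# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_col labs facet_wrap theme_minimal
NULL

#' Plot the mutation spectrum of an editing report
#'
#' @param object An `editing_report`.
#' @param ... Unused.
#' @return A ggplot: signature frequencies, descending.
#' @export
autoplot.editing_report <- function(object, ...) {
  sp <- object$spectrum
  sp$signature <- factor(sp$signature, levels = rev(sp$signature))
  ggplot(sp, aes(x = .data$frequency, y = .data$signature)) +
    geom_col(fill = "#2c7fb8") +
    labs(title = object$site_name,
         subtitle = sprintf("efficiency %.1f%% (%d / %d reads)",
                            100 * object$efficiency, object$mutant_reads,
                            object$total_reads),
         x = "read frequency", y = NULL) +
    theme_minimal()
}

#' Plot indel-profile histograms
#'
#' Four panels: indel-size distribution, insertion positions, deletion
#' start and end positions (PAM-relative; -1 is 1 nt upstream of the
#' PAM).
#'
#' @param object A `mutation_profile` ([summarize_mutation_profile()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mutation_profile <- function(object, ...) {
  df <- bind_rows(
    mutate(object$size_histogram, panel = "indel size",
           x = .data$key),
    mutate(object$insertion_position_histogram,
           panel = "insertion position", x = as.character(.data$position)),
    mutate(object$deletion_start_histogram, panel = "deletion start",
           x = as.character(.data$position)),
    mutate(object$deletion_end_histogram, panel = "deletion end",
           x = as.character(.data$position)))
  ggplot(df, aes(x = .data$x, y = .data$n)) +
    geom_col(fill = "#31a354") +
    facet_wrap(~panel, scales = "free") +
    labs(x = NULL, y = "records") +
    theme_minimal()
}

#' Histogram of mismatch counts among retained cleavage sites
#'
#' @param filtered Output of [filter_cleavage_candidates()] (or any
#'   tibble with `guide` and `mismatches`).
#' @return A ggplot of site counts per mismatch count, filled by guide.
#' @export
plot_mismatch_histogram <- function(filtered) {
  ggplot(filtered, aes(x = factor(.data$mismatches), fill = .data$guide)) +
    ggplot2::geom_bar() +
    labs(x = "mismatches to protospacer", y = "sites") +
    theme_minimal()
}

#' Tidy a consensus variant set
#'
#' @param x An `editscan_consensus` tibble.
#' @param ... Unused.
#' @return A flat tibble with the caller list collapsed to a string.
#' @export
tidy.editscan_consensus <- function(x, ...) {
  out <- as_tibble(x)
  out$callers <- vapply(out$callers, paste, character(1), collapse = ",")
  out
}

#' Summarise a consensus variant set
#'
#' @param x An `editscan_consensus` tibble.
#' @param ... Unused.
#' @return One row per variant class with counts and mean depth.
#' @export
glance.editscan_consensus <- function(x, ...) {
  as_tibble(x) %>%
    group_by(.data$vclass) %>%
    summarise(n = dplyr::n(),
              mean_alt_depth = mean(.data$max_alt_depth),
              .groups = "drop")
}
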
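#' Order diverging structures chronologically
#'
#' Keeps case-smaller diverged structures only (a larger-than-healthy
#' divergence is an anomaly, not atrophy) and sorts them by onset age
#' ascending; ties are broken by larger absolute distance at the
#' reference age, then by structure name.
#'
#' @param div_table a [divergence_table()] data.frame (or list of
#'   `divergence_result` objects).
#' @return the ordered subset of the table.
#' @export
order_structures <- function(div_table) {
  if (is.list(div_table) && !is.data.frame(div_table)) {
    div_table <- divergence_table(div_table)
  }
  keep <- div_table[div_table$diverged &
                    div_table$direction == "case_smaller", , drop = FALSE]
  if (nrow(keep) == 0L) return(keep)
  ord <- order(keep$onset_age, -abs(keep$distance_at_ref), keep$structure)
  out <- keep[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group chronologically ordered divergences into anatomical stages
#'
#' Walks the entries in onset order; an entry joins the current stage
#' when its onset is within `gap_threshold` years of the previous entry
#' or when it shares an anatomical group with a member of the current
#' stage; otherwise it opens a new stage. Stage indices run 1..S in
#' onset order.
#'
#' @param ordered output of [order_structures()].
#' @param grouping_map named character vector, structure -> anatomical
#'   group (e.g. putamen/caudate/accumbens -> striatum). Default: each
#'   structure is its own group. A supplied map must cover every entry.
#' @param gap_threshold years (default 2); onset gaps up to this merge.
#' @return object of class `staging_scheme`: `entries` (data.frame with
#'   `structure`, `onset_age`, `distance_at_ref`, `stage_index`,
#'   `anatomical_group`), `gap_threshold`, `grouping_map`.
#' @export
#' @examples
#' tab <- data.frame(structure = c("A", "B", "C"), diverged = TRUE,
#'                   onset_age = c(40, 40.5, 48), distance_at_ref = 1:3,
#'                   direction = "case_smaller")
#' group_stages(order_structures(tab), gap_threshold = 2)$entries
group_stages <- function(ordered, grouping_map = NULL, gap_threshold = 2) {
  default_map <- is.null(grouping_map)
  if (nrow(ordered) == 0L) {
    entries <- cbind(ordered[, c("structure", "onset_age",
                                 "distance_at_ref"), drop = FALSE],
                     stage_index = integer(0), anatomical_group = character(0))
    return(structure(list(entries = entries, gap_threshold = gap_threshold,
                          grouping_map = grouping_map %||% character()),
                     class = "staging_scheme"))
  }
  if (default_map) {
    grouping_map <- stats::setNames(ordered$structure, ordered$structure)
  } else {
    missing <- setdiff(ordered$structure, names(grouping_map))
    if (length(missing)) {
      stop("grouping map does not cover: ", paste(missing, collapse = ", "))
    }
  }
  grp <- unname(grouping_map[ordered$structure])
  stage <- integer(nrow(ordered))
  stage[1L] <- 1L
  stage_groups <- list(grp[1L])
  for (i in seq_len(nrow(ordered))[-1L]) {
    close_in_time <- ordered$onset_age[i] - ordered$onset_age[i - 1L] <=
      gap_threshold
    same_group <- grp[i] %in% stage_groups[[stage[i - 1L]]]
    if (close_in_time || same_group) {
      stage[i] <- stage[i - 1L]
      stage_groups[[stage[i]]] <- union(stage_groups[[stage[i]]], grp[i])
    } else {
      stage[i] <- stage[i - 1L] + 1L
      stage_groups[[stage[i]]] <- grp[i]
    }
  }
  entries <- data.frame(structure = ordered$structure,
                        onset_age = ordered$onset_age,
                        distance_at_ref = ordered$distance_at_ref,
                        stage_index = stage, anatomical_group = grp,
                        stringsAsFactors = FALSE)
  structure(list(entries = entries, gap_threshold = gap_threshold,
                 grouping_map = grouping_map),
            class = "staging_scheme")
}

#' Build a staging scheme from divergence results
#'
#' Chronological ordering ([order_structures()]) followed by stage
#' grouping ([group_stages()]): the machine-readable staging timeline.
#'
#' @param results divergence results (list or [divergence_table()]).
#' @inheritParams group_stages
#' @return a `staging_scheme`.
#' @export
staging_scheme <- function(results, grouping_map = NULL, gap_threshold = 2) {
  group_stages(order_structures(results), grouping_map = grouping_map,
               gap_threshold = gap_threshold)
}

#' @export
print.staging_scheme <- function(x, ...) {
  e <- x$entries
  if (nrow(e) == 0L) {
    cat("Staging scheme: no diverging structures\n")
    return(invisible(x))
  }
  cat(sprintf("Staging scheme: %d structures in %d stages (gap threshold %g y)\n",
              nrow(e), max(e$stage_index), x$gap_threshold))
  for (s in unique(e$stage_index)) {
    sub <- e[e$stage_index == s, ]
    cat(sprintf("  stage %d (%.1f-%.1f y): %s\n", s, min(sub$onset_age),
                max(sub$onset_age),
                paste(sprintf("%s (%.1f y, d=%.2f)", sub$structure,
                              sub$onset_age, sub$distance_at_ref),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Timeline plot of a staging scheme
#'
#' Onset age on the x axis, one labelled marker per structure,
#' colour-coded by the severity score (distance at the reference age).
#'
#' @param x a `staging_scheme`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.staging_scheme <- function(x, ...) {
  e <- x$entries
  if (nrow(e) == 0L) {
    graphics::plot.new()
    graphics::title("No diverging structures")
    return(invisible(x))
  }
  sev <- abs(e$distance_at_ref)
  pal <- grDevices::colorRampPalette(c("gold", "orangered", "darkred"))(100)
  idx <- 1 + round(99 * (sev - min(sev)) /
                     max(1e-12, diff(range(sev))))
  y <- rev(seq_len(nrow(e)))
  graphics::plot(e$onset_age, y, pch = 19, cex = 1.6, col = pal[idx],
                 yaxt = "n", ylab = "", xlab = "divergence onset (years)",
                 main = "Atrophy staging timeline",
                 xlim = range(e$onset_age) + c(-2, 10), ...)
  graphics::text(e$onset_age, y,
                 sprintf("%s (stage %d)", e$structure, e$stage_index),
                 pos = 4, cex = 0.8)
  invisible(x)
}

#' Rank structures by severity at the reference age
#'
#' Diverged structures sorted by absolute distance at the reference age,
#' descending (the "most affected over time" ranking); ties broken by
#' structure name.
#'
#' @param div_table divergence results (list or [divergence_table()]).
#' @param top_k how many to return (default: all).
#' @return data.frame subset in rank order.
#' @export
rank_severity <- function(div_table, top_k = Inf) {
  if (is.list(div_table) && !is.data.frame(div_table)) {
    div_table <- divergence_table(div_table)
  }
  if (nrow(div_table) == 0L) return(div_table)
  keep <- div_table[div_table$diverged, , drop = FALSE]
  ord <- order(-abs(keep$distance_at_ref), keep$structure)
  out <- keep[ord, , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n = if (is.finite(top_k)) top_k else nrow(out))
}
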
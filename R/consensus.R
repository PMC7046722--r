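#' Default per-tool deleteriousness cutoff rules
#'
#' The eight predictor cutoffs applied to variant score tables:
#' SIFT = 0, PolyPhen-2 > 0.9, PROVEAN < -2.5, I-Mutant < -0.5 (a
#' destabilising ddG), FATHMM |score| > 3.0 (the two-tailed reading of
#' "< -3.0 or > 3.0"), MutPred > 0.75, CADD > 20, Condel > 0.8. The SIFT
#' equality is implemented as score <= 1e-9, since SIFT reports 0.00 for
#' fully intolerant positions.
#'
#' @return data.frame with columns \code{tool}, \code{direction}
#'   (one of \code{"eq0"}, \code{"gt"}, \code{"lt"}, \code{"abs_gt"}),
#'   \code{threshold}.
#' @export
default_cutoff_rules <- function() {
  data.frame(
    tool = c("SIFT", "PolyPhen2", "PROVEAN", "IMutant", "FATHMM",
             "MutPred", "CADD", "Condel"),
    direction = c("eq0", "gt", "lt", "lt", "abs_gt", "gt", "gt", "gt"),
    threshold = c(0, 0.9, -2.5, -0.5, 3.0, 0.75, 20, 0.8),
    stringsAsFactors = FALSE
  )
}

.rule_fires <- function(score, direction, threshold) {
  switch(direction,
         eq0    = score <= threshold + 1e-9,
         gt     = score > threshold,
         lt     = score < threshold,
         abs_gt = abs(score) > threshold,
         stop("unknown cutoff direction '", direction, "'"))
}

#' Classify one variant's scores against the cutoff rules
#'
#' @param scores named numeric vector of tool scores (NA = not scored).
#' @param rules cutoff rules (default \code{\link{default_cutoff_rules}}).
#' @return list with \code{flags} (named logical, NA where unscored),
#'   \code{deleterious_count}, \code{n_tools_scored}.
#' @export
classify_variant <- function(scores, rules = default_cutoff_rules()) {
  tools <- names(scores)
  unknown <- setdiff(tools, rules$tool)
  if (length(unknown) > 0L) {
    stop("no cutoff rule for tool(s): ", paste(unknown, collapse = ", "))
  }
  flags <- stats::setNames(rep(NA, length(tools)), tools)
  for (tl in tools) {
    s <- scores[[tl]]
    if (is.na(s)) next
    if (!is.finite(s)) stop("non-finite score for ", tl)
    r <- rules[rules$tool == tl, ]
    flags[tl] <- .rule_fires(s, r$direction, r$threshold)
  }
  list(flags = flags,
       deleterious_count = sum(flags, na.rm = TRUE),
       n_tools_scored = sum(!is.na(flags)))
}

#' Rank variants by deleteriousness consensus
#'
#' Applies every tool's cutoff rule to each variant, counts deleterious
#' calls, and orders variants by descending count with alphabetical
#' tie-breaking — the ordering under which a variant flagged by all eight
#' tools (as W50C was) ranks first.
#'
#' @param table data.frame of variant scores: either wide (one row per
#'   variant, rownames or a \code{variant} column plus one column per tool)
#'   or long (columns \code{variant}, \code{tool}, \code{score}).
#' @param rules cutoff rules (default \code{\link{default_cutoff_rules}}).
#' @return data.frame (class \code{"ConsensusResult"}) with one row per
#'   variant: \code{variant}, one logical column per tool,
#'   \code{deleterious_count}, \code{n_tools_scored}, \code{rank}.
#' @export
consensus_rank <- function(table, rules = default_cutoff_rules()) {
  wide <- .scores_to_wide(table)
  if (nrow(wide) == 0L) stop("empty variant score table")
  tools <- setdiff(names(wide), "variant")
  res <- lapply(seq_len(nrow(wide)), function(i) {
    s <- stats::setNames(as.numeric(wide[i, tools]), tools)
    classify_variant(s, rules)
  })
  out <- data.frame(variant = wide$variant, stringsAsFactors = FALSE)
  for (tl in tools) out[[tl]] <- vapply(res, function(r) r$flags[[tl]], logical(1))
  out$deleterious_count <- vapply(res, function(r) r$deleterious_count, numeric(1))
  out$n_tools_scored <- vapply(res, function(r) r$n_tools_scored, numeric(1))
  out <- out[order(-out$deleterious_count, out$variant), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("ConsensusResult", "data.frame")
  out
}

# accept wide or long score tables
.scores_to_wide <- function(table) {
  table <- as.data.frame(table)
  if (all(c("variant", "tool", "score") %in% names(table))) {
    wide <- stats::reshape(table[, c("variant", "tool", "score")],
                           idvar = "variant", timevar = "tool",
                           direction = "wide")
    names(wide) <- sub("^score\\.", "", names(wide))
    rownames(wide) <- NULL
    return(wide)
  }
  if (!"variant" %in% names(table)) {
    table <- cbind(variant = rownames(table), table)
  }
  table$variant <- as.character(table$variant)
  table
}

#' Read a variant score table from CSV (wide or long layout)
#' @param path CSV file.
#' @return wide data.frame with a \code{variant} column.
#' @export
read_score_table <- function(path) {
  .scores_to_wide(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a consensus result as CSV
#' @param x a \code{ConsensusResult}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_consensus_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
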
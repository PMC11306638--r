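#' Read a pathway direction table
#'
#' TSV with columns `pathway_id`, `term`, `direction_a`, `direction_b`
#' (each `"up"`/`"down"`) and `available` (logical). Directions are only
#' required on available rows.
#'
#' @param path TSV file.
#' @return validated data frame.
#' @export
read_direction_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", na.strings = "",
                           stringsAsFactors = FALSE)
  need <- c("pathway_id", "term", "direction_a", "direction_b", "available")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("direction table lacks columns: ",
                         paste(miss, collapse = ", "))
  tab$available <- as.logical(tab$available)
  av <- tab[tab$available, ]
  bad <- !av$direction_a %in% c("up", "down") | !av$direction_b %in% c("up", "down")
  if (any(bad)) stop("direction table: available rows must have up/down directions (row ",
                     which(bad)[1], " of available rows)")
  tab
}

#' One-sided binomial test of direction opposition
#'
#' Counts the available pathways whose directions under the two
#' perturbations disagree, and returns the exact one-sided binomial tail
#' `P(X >= k | n, 1/2)` — the probability of at least this much opposition
#' if directions were independent coin flips. One-sided because the
#' alternative of interest is that opposition is *more* frequent than
#' chance.
#'
#' @param table direction table (see [read_direction_table()]).
#' @return list: `k` (opposite-direction count), `n` (available rows),
#'   `p_one_sided`.
#' @export
opposite_direction_binomial <- function(table) {
  av <- table[table$available, , drop = FALSE]
  n <- nrow(av)
  if (n == 0) stop("opposite_direction_binomial: no available rows")
  k <- sum(av$direction_a != av$direction_b)
  p <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  list(k = k, n = n, p_one_sided = p)
}

#' Fisher's exact test of term-specific direction bias
#'
#' Builds the 2x2 table of (term matches pattern) x (direction down vs up)
#' for one condition's direction column, and returns the exact two-sided
#' hypergeometric p (sum of tables as or less probable than observed).
#'
#' @param table direction table.
#' @param term_pattern regular expression matched (case-insensitively)
#'   against the `term` column.
#' @param condition `"a"` or `"b"`: which direction column to test.
#' @return list: `contingency` (2x2 matrix), `p_two_sided`.
#' @export
term_direction_fisher <- function(table, term_pattern, condition = c("a", "b")) {
  condition <- match.arg(condition)
  av <- table[table$available, , drop = FALSE]
  if (nrow(av) == 0) stop("term_direction_fisher: no available rows")
  hit <- grepl(term_pattern, av$term, ignore.case = TRUE)
  if (!any(hit)) stop("term_direction_fisher: pattern matches no rows")
  dirn <- av[[paste0("direction_", condition)]]
  tab <- matrix(c(
    sum(hit & dirn == "down"), sum(hit & dirn == "up"),
    sum(!hit & dirn == "down"), sum(!hit & dirn == "up")
  ), nrow = 2, byrow = TRUE,
  dimnames = list(term = c("match", "other"), direction = c("down", "up")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("term_direction_fisher: degenerate margin in the 2x2 table")
  }
  p <- stats::fisher.test(tab)$p.value
  list(contingency = tab, p_two_sided = p)
}
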
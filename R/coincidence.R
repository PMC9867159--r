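#' Cross-method coincidence ranking
#'
#' Fuses several feature rankings by intersection: a feature qualifies if
#' it appears in the top-`window` of every method; its final rank is the
#' best (numerically smallest) rank it attains across methods; candidates
#' whose final rank is `max_rank` or worse are discarded. The report is
#' sorted by final rank (ties broken by feature name) and each feature is
#' assigned a rank-interval bucket (`"<10"`, `"<20"`, ...).
#'
#' @param rankings List of two or more `ranking_result` objects over the
#'   same feature set.
#' @param window Only features in every method's top-`window` qualify
#'   (default 30).
#' @param max_rank Features with final rank at or above this are dropped
#'   (default 50).
#' @return A data.frame with columns `feature`, `final_rank`, `bucket`,
#'   and one rank column per method.
#' @export
coincidence <- function(rankings, window = 30L, max_rank = 50L) {
  if (length(rankings) < 2) stop("need at least two rankings")
  fn <- names(rankings[[1]]$scores)
  for (r in rankings) {
    if (!setequal(names(r$scores), fn)) stop("rankings cover different feature sets")
  }
  methods <- vapply(rankings, function(r) r$method, character(1))
  methods <- make.unique(methods)
  # rank position of every feature in every method
  pos <- vapply(rankings, function(r) match(fn, r$order), integer(length(fn)))
  rownames(pos) <- fn
  colnames(pos) <- methods

  in_all <- apply(pos <= window, 1, all)
  final <- apply(pos, 1, min)
  keep <- in_all & final < max_rank
  out <- data.frame(feature = fn[keep], final_rank = final[keep],
                    stringsAsFactors = FALSE)
  out <- cbind(out, pos[keep, , drop = FALSE])
  out <- out[order(out$final_rank, out$feature), , drop = FALSE]
  edges <- sort(unique(c(10L, 20L, 30L, 50L, as.integer(ceiling(max_rank / 10) * 10))))
  out$bucket <- vapply(out$final_rank,
                       function(r) paste0("<", edges[which(r < edges)[1]]),
                       character(1))
  rownames(out) <- NULL
  out[, c("feature", "final_rank", "bucket", methods)]
}
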
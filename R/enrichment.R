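#' Hypergeometric over-representation of a dataset in a gene list
#'
#' One-sided upper-tail hypergeometric test of whether a dataset's hits are
#' over-represented in a gene list relative to a background universe:
#' the probability of observing at least `hits_in_list` successes when
#' `list_size` genes are drawn without replacement from a universe of
#' `background_size` genes containing `background_hits` successes.
#' Significance stars follow the usual thresholds (`*` p < 0.05, `**`
#' p < 0.01, `***` p < 0.001, `ns` otherwise). The background universe is a
#' required input; there is no default genome size.
#'
#' @param hits_in_list observed hits in the list (<= `list_size`).
#' @param list_size size of the gene list.
#' @param background_hits successes in the background universe.
#' @param background_size size of the background universe.
#' @param dataset_id optional label carried into the result.
#' @return data.frame with the four counts, `p_value` and `stars`. All
#'   arguments are vectorised.
#' @examples
#' dataset_enrichment(5, 5, 5, 10)   # p = 1/252, "**"
#' @export
dataset_enrichment <- function(hits_in_list, list_size, background_hits,
                               background_size, dataset_id = NA_character_) {
  n <- max(length(hits_in_list), length(list_size), length(background_hits),
           length(background_size))
  hits_in_list <- rep_len(hits_in_list, n)
  list_size <- rep_len(list_size, n)
  background_hits <- rep_len(background_hits, n)
  background_size <- rep_len(background_size, n)
  dataset_id <- rep_len(dataset_id, n)
  if (any(hits_in_list > list_size))
    stop("hits_in_list cannot exceed list_size")
  if (any(background_hits > background_size))
    stop("background_hits cannot exceed background_size")
  if (any(list_size > background_size))
    stop("list_size cannot exceed background_size")
  if (any(hits_in_list > background_hits))
    stop("hits_in_list cannot exceed background_hits")
  if (any(c(hits_in_list, list_size, background_hits, background_size) < 0))
    stop("counts must be non-negative")
  p <- stats::phyper(hits_in_list - 1, background_hits,
                     background_size - background_hits, list_size,
                     lower.tail = FALSE)
  stars <- cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", "ns"), right = FALSE)
  data.frame(dataset_id = dataset_id, hits_in_list = hits_in_list,
             list_size = list_size, background_hits = background_hits,
             background_size = background_size, p_value = p,
             stars = as.character(stars), stringsAsFactors = FALSE)
}
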
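#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @method tidy hap_network
#' @rdname hap_network_tidiers
#' @param x A `hap_network` or `fst_result`.
#' @param ... Unused.
tidy.hap_network <- function(x, ...) x$edges

#' Tidiers for haplotype networks and Fst results
#'
#' `tidy()` returns the per-edge / per-site table; `glance()` a one-row
#' summary.
#'
#' @name hap_network_tidiers
#' @export
#' @method glance hap_network
glance.hap_network <- function(x, ...) {
  tibble(n_haplotypes = nrow(x$nodes),
         n_sequences = sum(x$nodes$count),
         n_tree_edges = sum(x$edges$in_mst),
         n_tie_edges = sum(x$edges$tie_edge))
}

#' @export
#' @method tidy fst_result
#' @rdname hap_network_tidiers
tidy.fst_result <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
#' @method glance fst_result
#' @rdname hap_network_tidiers
glance.fst_result <- function(x, ...) {
  tibble(mean_fst = attr(x, "mean_fst"),
         n_sites = nrow(x), n_defined = sum(!is.na(x$fst)))
}

#' @export
#' @method tidy demux_result
#' @rdname hap_network_tidiers
tidy.demux_result <- function(x, ...) x$summary

#' @export
#' @method glance demux_result
#' @rdname hap_network_tidiers
glance.demux_result <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs),
         n_assigned = sum(!is.na(x$pairs$sample_id)),
         n_unassigned = sum(is.na(x$pairs$sample_id)),
         n_samples = length(unique(stats::na.omit(x$pairs$sample_id))))
}
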
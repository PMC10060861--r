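#' Canonical seven-network labels
#'
#' The seven resting-state networks of the canonical cortical parcellation,
#' in the order used throughout the package.
#'
#' @return Character vector of length 7.
#' @export
network_labels <- function() {
  c("default", "somatomotor", "control", "dorsoattention",
    "salience_ventral_attention", "limbic", "visual")
}

#' Build the default node-to-network partition
#'
#' A 100-node, 7-network partition table in the style of the canonical
#' 100-parcel cortical atlas: every node carries exactly one network label
#' and every network has at least two nodes. Node ids are 1-based. The
#' per-network node counts approximate the proportions of the canonical
#' atlas (the default-mode network is the largest system); exact parcel
#' membership is irrelevant here because only the grouping enters the
#' segregation computation.
#'
#' @param n_nodes Total number of nodes. The default 100 gives the canonical
#'   sizes; other values distribute nodes proportionally (each network keeps
#'   at least 2 nodes).
#' @return A tibble with columns `node_id` (integer), `node_label`
#'   (character) and `network` (factor with the seven canonical levels).
#' @examples
#' canonical_partition()
#' @export
canonical_partition <- function(n_nodes = 100) {
  stopifnot(is.numeric(n_nodes), length(n_nodes) == 1, n_nodes >= 14)
  nets <- network_labels()
  base <- c(default = 22, somatomotor = 15, control = 13, dorsoattention = 13,
            salience_ventral_attention = 12, limbic = 10, visual = 15)
  if (n_nodes == 100) {
    sizes <- base
  } else {
    sizes <- pmax(2L, round(base / 100 * n_nodes))
    # adjust the largest network so the sizes sum exactly
    sizes[1] <- sizes[1] + (n_nodes - sum(sizes))
    if (sizes[1] < 2) stop("n_nodes too small for a 7-network partition")
  }
  network <- factor(rep(nets, times = sizes[nets]), levels = nets)
  tibble::tibble(
    node_id = seq_len(n_nodes),
    node_label = sprintf("node_%03d_%s", seq_len(n_nodes), as.character(network)),
    network = network
  )
}

#' Validate a partition table
#'
#' Checks the invariants the segregation computation relies on: one network
#' per node, no missing labels, and at least two nodes per network (a
#' single-node network has no within-network pair, so its W is undefined).
#'
#' @param partition A data frame with at least a `network` column; `node_id`
#'   is added (row order) when absent.
#' @return The partition as a tibble with `node_id` and `network` columns,
#'   invisibly usable downstream.
#' @export
validate_partition <- function(partition) {
  stopifnot(is.data.frame(partition), "network" %in% names(partition))
  out <- tibble::as_tibble(partition)
  if (!"node_id" %in% names(out)) out$node_id <- seq_len(nrow(out))
  if (anyNA(out$network)) stop("partition has unlabeled nodes")
  if (anyDuplicated(out$node_id)) stop("duplicated node_id in partition")
  sizes <- table(as.character(out$network))
  if (any(sizes < 2)) {
    stop("networks with fewer than 2 nodes (within-network connectivity undefined): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  out
}

#' Read a partition lookup table
#'
#' Reads a two-column text table (`node_label`, `network`; TSV or CSV,
#' detected from the extension) and returns a validated partition.
#'
#' @param path Path to the table.
#' @return A partition tibble (see [canonical_partition()]).
#' @export
read_partition <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  tab <- reader(path, show_col_types = FALSE)
  if (!all(c("node_label", "network") %in% names(tab))) {
    stop("partition table must have columns 'node_label' and 'network'")
  }
  tab$node_id <- seq_len(nrow(tab))
  validate_partition(tab[, c("node_id", "node_label", "network")])
}
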
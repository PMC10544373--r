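#' Virus-host evidence from bin co-membership
#'
#' A (virus, host) pair is linked when a viral contig was placed in the same
#' bin as a host genome's contigs during metagenomic binning.
#'
#' @param virus_bins data.frame with `contig_id`, `bin_id`, `genome_id`
#'   (viral contigs; `genome_id` is usually the contig itself).
#' @param host_bins data.frame with `contig_id`, `bin_id`, `genome_id`
#'   (host MAG membership).
#' @return data.frame of evidence: `virus_id`, `host_id`, `channel` ("bin"),
#'   `score` (the shared bin id). A contig assigned to two bins is an error.
#' @export
bin_comembership <- function(virus_bins, host_bins) {
  for (tb in list(virus_bins, host_bins)) {
    dup <- unique(tb[, c("contig_id", "bin_id")])
    if (anyDuplicated(dup$contig_id))
      stop("contig assigned to more than one bin: ",
           dup$contig_id[duplicated(dup$contig_id)][1])
  }
  mg <- merge(unique(virus_bins[, c("genome_id", "bin_id")]),
              unique(host_bins[, c("genome_id", "bin_id")]),
              by = "bin_id", suffixes = c("_virus", "_host"))
  if (!nrow(mg))
    return(data.frame(virus_id = character(), host_id = character(),
                      channel = character(), score = character(),
                      stringsAsFactors = FALSE))
  out <- unique(data.frame(virus_id = mg$genome_id_virus,
                           host_id = mg$genome_id_host,
                           channel = "bin", score = mg$bin_id,
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out[order(out$virus_id, out$host_id), , drop = FALSE]
}

#' Integrate virus-host evidence into an interaction network
#'
#' Collapses per-channel evidence rows into distinct (virus, host) edges
#' with the set of supporting channels and a consensus count; viruses are
#' labelled virulent/temperate from their lifestyle score and classified as
#' specialist (one host) or generalist (several).
#'
#' @param evidence data.frame (or list of data.frames, rbind-compatible on
#'   `virus_id`, `host_id`, `channel`) from the four evidence channels.
#' @param lifestyles named numeric vector virus -> lifestyle score, or
#'   data.frame with `virus_id`, `score`. Scores on \[0, 1\] by default.
#' @param taxonomy host taxonomy from [parse_taxonomy()].
#' @param score_scale 1 (scores in \[0,1\], virulent >= 0.5) or 100
#'   (percentage scores, virulent >= 50).
#' @return Object of class `host_network`: list with `edges` (`virus_id`,
#'   `host_id`, `channels`, `consensus`), `viruses` (`virus_id`, `score`,
#'   `lifestyle`, `n_hosts`, `role`), `hosts` (taxonomy + `n_viruses`),
#'   `phylum_tally`, `genus_tally`. Evidence naming an id missing from
#'   `lifestyles`/`taxonomy` is an error.
#' @export
integrate_evidence <- function(evidence, lifestyles, taxonomy,
                               score_scale = 1) {
  if (is.list(evidence) && !is.data.frame(evidence))
    evidence <- do.call(rbind, lapply(evidence, function(e)
      e[, c("virus_id", "host_id", "channel")]))
  else evidence <- evidence[, c("virus_id", "host_id", "channel")]
  if (is.data.frame(lifestyles))
    lifestyles <- setNames(lifestyles$score, lifestyles$virus_id)
  if (nrow(evidence)) {
    unknown_v <- setdiff(evidence$virus_id, names(lifestyles))
    if (length(unknown_v))
      stop("evidence references unknown virus id(s): ",
           paste(head(unknown_v, 3), collapse = ", "))
    unknown_h <- setdiff(evidence$host_id, taxonomy$genome_id)
    if (length(unknown_h))
      stop("evidence references unknown host id(s): ",
           paste(head(unknown_h, 3), collapse = ", "))
  }
  evidence <- unique(evidence)
  key <- paste(evidence$virus_id, evidence$host_id, sep = "\r")
  ch <- split(evidence$channel, key)
  pairs <- do.call(rbind, strsplit(names(ch), "\r", fixed = TRUE))
  edges <- if (length(ch)) data.frame(
    virus_id = pairs[, 1], host_id = pairs[, 2],
    channels = vapply(ch, function(x) paste(sort(unique(x)), collapse = ","),
                      character(1)),
    consensus = vapply(ch, function(x) length(unique(x)), integer(1)),
    stringsAsFactors = FALSE)
  else data.frame(virus_id = character(), host_id = character(),
                  channels = character(), consensus = integer(),
                  stringsAsFactors = FALSE)
  edges <- edges[order(edges$virus_id, edges$host_id), , drop = FALSE]
  rownames(edges) <- NULL

  cut <- score_scale * 0.5
  vids <- sort(unique(edges$virus_id))
  nh <- table(edges$virus_id)
  viruses <- data.frame(
    virus_id = vids,
    score = unname(lifestyles[vids]),
    lifestyle = ifelse(lifestyles[vids] >= cut, "virulent", "temperate"),
    n_hosts = as.integer(nh[vids]),
    stringsAsFactors = FALSE)
  viruses$role <- ifelse(viruses$n_hosts == 1, "specialist", "generalist")

  hids <- sort(unique(edges$host_id))
  tx <- taxonomy[match(hids, taxonomy$genome_id), , drop = FALSE]
  hosts <- data.frame(tx, n_viruses = as.integer(table(edges$host_id)[hids]),
                      stringsAsFactors = FALSE, row.names = NULL)

  ph <- taxonomy$phylum[match(edges$host_id, taxonomy$genome_id)]
  gn <- taxonomy$genus[match(edges$host_id, taxonomy$genome_id)]
  structure(list(edges = edges, viruses = viruses, hosts = hosts,
                 phylum_tally = sort(table(ph), decreasing = TRUE),
                 genus_tally = sort(table(gn), decreasing = TRUE),
                 taxonomy = taxonomy),
            class = "host_network")
}

#' @export
print.host_network <- function(x, ...) {
  cat("Virus-host interaction network\n")
  cat("  edges:", nrow(x$edges), " viruses:", nrow(x$viruses),
      " hosts:", nrow(x$hosts), "\n")
  if (nrow(x$edges)) {
    cat("  consensus >= 2:", sum(x$edges$consensus >= 2),
        sprintf("(%.1f%%)\n", 100 * mean(x$edges$consensus >= 2)))
    cat("  specialists:", sum(x$viruses$role == "specialist"),
        sprintf("(%.1f%%)\n", 100 * mean(x$viruses$role == "specialist")))
  }
  invisible(x)
}

#' Screen the network for viruses targeting methanogens
#'
#' Restricts the network to edges whose host genus is a methanogen (archaeal
#' kingdom enforced) and reports all targeting viruses plus the putative
#' lytic (virulent) subset.
#'
#' @param net a `host_network` from [integrate_evidence()].
#' @param methanogen_genera genus names counted as methanogens; defaults to
#'   the four methanogen genera of the goat GIT catalog.
#' @return List with `edges` (subnetwork, plus `multi_method` flag for
#'   consensus >= 2), `targeting_viruses`, `lytic_viruses`.
#' @export
methanogen_screen <- function(net,
                              methanogen_genera = c("Methanomethylophilus",
                                                    "Methanocorpusculum",
                                                    "Methanobrevibacter_A",
                                                    "ISO4-G1")) {
  if (!length(methanogen_genera)) stop("methanogen genus set is empty")
  tx <- net$taxonomy
  idx <- match(net$edges$host_id, tx$genome_id)
  is_meth <- tx$genus[idx] %in% methanogen_genera &
    tx$kingdom[idx] == "archaea"
  edges <- net$edges[is_meth, , drop = FALSE]
  edges$multi_method <- edges$consensus >= 2
  rownames(edges) <- NULL
  targeting <- sort(unique(edges$virus_id))
  lytic <- intersect(targeting,
                     net$viruses$virus_id[net$viruses$lifestyle == "virulent"])
  list(edges = edges, targeting_viruses = targeting,
       lytic_viruses = sort(lytic))
}
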
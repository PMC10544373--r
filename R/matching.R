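#' Match CRISPR spacers against viral genomes
#'
#' Exhaustive ungapped search of every spacer (both strands) against every
#' virus. A hit is retained when it has at most `max_mismatch` substitutions
#' over an aligned span longer than `min_cov` times the spacer length;
#' terminal overhangs (spacer ends hanging off a virus end) shorten the span
#' and are not counted as mismatches. One evidence row per (virus, host)
#' pair keeps the best (fewest-mismatch, then longest-span) hit.
#'
#' @param spacers data.frame with columns `host_id` and `spacer_seq` (e.g.
#'   from [detect_crispr()]).
#' @param viruses named character vector / `DNAStringSet` of virus genomes.
#' @param max_mismatch maximum substitutions (default 1).
#' @param min_cov minimum aligned fraction of the spacer, strict (default
#'   0.95).
#' @return data.frame of evidence: `virus_id`, `host_id`, `channel`
#'   ("crispr"), `score` (mismatches), `virus_start`, `virus_end` (0-based
#'   half-open, forward coordinates), `strand`, `span`.
#' @export
match_spacers <- function(spacers, viruses, max_mismatch = 1, min_cov = 0.95) {
  viruses <- as_seq_vector(viruses)
  if (!nrow(spacers)) stop("spacers must be non-empty")
  vcodes <- lapply(viruses, dna_to_int)
  vcodes_rc <- lapply(viruses, function(s) dna_to_int(revcomp_chr(s)))

  best <- list()
  for (i in seq_len(nrow(spacers))) {
    sp <- spacers$spacer_seq[i]
    host <- spacers$host_id[i]
    plen <- nchar(sp)
    if (plen < 10) { message("spacer shorter than seed length skipped"); next }
    pat <- dna_to_int(sp)
    max_ov <- floor(plen * (1 - min_cov) - 1e-9) # span must be > min_cov*plen
    for (vid in names(viruses)) {
      L <- length(vcodes[[vid]])
      for (strand in c("+", "-")) {
        subj <- if (strand == "+") vcodes[[vid]] else vcodes_rc[[vid]]
        hit <- scan_best_hit(subj, pat, max_mismatch, max_ov)
        if (is.null(hit)) next
        # convert to forward-strand virus coordinates (0-based half-open)
        if (strand == "+") {
          vs <- hit$start; ve <- hit$start + hit$span
        } else {
          ve <- L - hit$start; vs <- ve - hit$span
        }
        key <- paste(vid, host, sep = "\r")
        prev <- best[[key]]
        if (is.null(prev) || hit$mm < prev$score ||
            (hit$mm == prev$score && hit$span > prev$span)) {
          best[[key]] <- list(virus_id = vid, host_id = host, score = hit$mm,
                              virus_start = vs, virus_end = ve,
                              strand = strand, span = hit$span)
        }
      }
    }
  }
  if (!length(best))
    return(data.frame(virus_id = character(), host_id = character(),
                      channel = character(), score = numeric(),
                      virus_start = integer(), virus_end = integer(),
                      strand = character(), span = integer(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(best, function(b)
    data.frame(virus_id = b$virus_id, host_id = b$host_id, channel = "crispr",
               score = b$score, virus_start = b$virus_start,
               virus_end = b$virus_end, strand = b$strand, span = b$span,
               stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df[order(df$virus_id, df$host_id), , drop = FALSE]
}

# best qualifying ungapped placement of pat in subj (integer codes, one
# strand): interior full-length placements plus terminal overhangs up to
# max_ov. Returns list(start 0-based, span, mm) or NULL.
scan_best_hit <- function(subj, pat, max_mismatch, max_ov) {
  plen <- length(pat)
  cand <- NULL
  take <- function(start0, span, mm) {
    if (mm <= max_mismatch &&
        (is.null(cand) || mm < cand$mm ||
         (mm == cand$mm && span > cand$span)))
      cand <<- list(start = start0, span = span, mm = mm)
  }
  if (length(subj) >= plen) {
    mms <- hamming_scan(as.integer(subj), as.integer(pat))
    if (length(mms)) {
      jbest <- which.min(mms)
      take(jbest - 1L, plen, mms[jbest])
    }
  }
  if (max_ov > 0) {
    for (ov in seq_len(max_ov)) {
      span <- plen - ov
      if (span > length(subj)) next
      # spacer 5' end hangs off the subject start
      mm <- sum(subj[seq_len(span)] != pat[(ov + 1L):plen])
      take(0L, span, mm)
      # spacer 3' end hangs off the subject end
      mm <- sum(subj[(length(subj) - span + 1L):length(subj)] !=
                  pat[seq_len(span)])
      take(length(subj) - span, span, mm)
    }
  }
  cand
}

#' Nucleotide-homology evidence between viruses and hosts
#'
#' Shared exact k-mer seeds (both strands) are grouped by alignment
#' diagonal; each seeded diagonal is scored base-by-base and the
#' maximal-scoring ungapped local segment (match +1, mismatch penalised at
#' the identity threshold's odds) is extracted. A (virus, host) pair yields
#' evidence when its best segment has identity > `min_identity` over
#' > `min_len` aligned bp; the longest accepted alignment is kept.
#'
#' @param viruses,hosts named character vectors / `DNAStringSet`.
#' @param min_identity strict identity threshold (default 0.90).
#' @param min_len strict minimum alignment length in bp (default 500).
#' @param seed_k exact seed length (default 11).
#' @return data.frame of evidence: `virus_id`, `host_id`, `channel`
#'   ("homology"), `score` (identity), `length`, `virus_start`,
#'   `host_start` (0-based), `strand`.
#' @export
match_homology <- function(viruses, hosts, min_identity = 0.90,
                           min_len = 500, seed_k = 11) {
  viruses <- as_seq_vector(viruses)
  hosts <- as_seq_vector(hosts)
  vfwd <- lapply(viruses, dna_to_int)
  vrev <- lapply(viruses, function(s) dna_to_int(revcomp_chr(s)))
  hcode <- lapply(hosts, dna_to_int)
  # mask seeds from repetitive/low-complexity words (> 5 copies in one
  # genome): they seed no usable diagonal but inflate the candidate set
  hkm <- lapply(hcode, function(cc) {
    km <- kmer_codes(cc, seed_k)
    tab <- table(km)
    km[km %in% as.numeric(names(tab)[tab > 5L])] <- NA_real_
    km
  })
  penalty <- min_identity / (1 - min_identity) # segment score >0 <=> id > thr

  rows <- list()
  for (vid in names(viruses)) {
    for (strand in c("+", "-")) {
      vcode <- if (strand == "+") vfwd[[vid]] else vrev[[vid]]
      vkm <- kmer_codes(vcode, seed_k)
      vtab <- table(vkm)
      vkm[vkm %in% as.numeric(names(vtab)[vtab > 5L])] <- NA_real_
      vkm_set <- vkm[!is.na(vkm)]
      vpos <- split(seq_along(vkm), vkm)
      for (hid in names(hosts)) {
        hits <- which(hkm[[hid]] %in% vkm_set)
        if (!length(hits)) next
        # seed pairs -> diagonals (host_pos - virus_pos)
        vlist <- vpos[as.character(hkm[[hid]][hits])]
        diag_h <- rep(hits, lengths(vlist))
        diag_v <- unlist(vlist, use.names = FALSE)
        diags <- diag_h - diag_v
        # a true >500 bp / >90% identity segment carries >100 exact 11-mer
        # seeds on one diagonal; sparse random seed collisions are skipped
        dtab <- table(diags)
        cand_diags <- as.integer(names(dtab)[dtab >= 15L])
        cand_diags <- cand_diags[vapply(cand_diags, function(dg) {
          sp <- diag_v[diags == dg]
          max(sp) - min(sp) >= min_len * 0.5
        }, logical(1))]
        best <- NULL
        for (dg in cand_diags) {
          seg <- best_diagonal_segment(hcode[[hid]], vcode, dg, penalty)
          if (is.null(seg)) next
          if (seg$len > min_len && seg$identity > min_identity &&
              (is.null(best) || seg$len > best$len)) best <- seg
        }
        if (!is.null(best)) {
          key <- paste(vid, hid, sep = "\r")
          prev <- rows[[key]]
          if (is.null(prev) || best$len > prev$length) {
            vs <- if (strand == "+") best$vstart else
              length(vcode) - (best$vstart + best$len)
            rows[[key]] <- data.frame(
              virus_id = vid, host_id = hid, channel = "homology",
              score = best$identity, length = best$len,
              virus_start = vs, host_start = best$hstart, strand = strand,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(virus_id = character(), host_id = character(),
                      channel = character(), score = numeric(),
                      length = integer(), virus_start = integer(),
                      host_start = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df[order(df$virus_id, df$host_id), , drop = FALSE]
}

# maximal-scoring ungapped segment along one diagonal (Kadane on +1 match /
# -penalty mismatch, vectorised via prefix sums); returns 0-based starts,
# length, identity
best_diagonal_segment <- function(hc, vc, dg, penalty) {
  # overlap range in virus coordinates (1-based)
  v1 <- max(1L, 1L - dg)
  v2 <- min(length(vc), length(hc) - dg)
  if (v2 - v1 < 1L) return(NULL)
  m <- hc[(v1 + dg):(v2 + dg)] == vc[v1:v2]
  pre <- c(0, cumsum(-penalty + (1 + penalty) * m))
  gain <- pre[-1] - cummin(pre[-length(pre)])
  j <- which.max(gain)
  if (gain[j] <= 0) return(NULL)
  i <- which.min(pre[seq_len(j)]) # segment = sc[i..j] in 1-based overlap coords
  len <- j - i + 1L
  ident <- sum(m[i:j]) / len
  list(vstart = v1 + i - 2L,                 # 0-based on the scanned strand
       hstart = v1 + dg + i - 2L,            # 0-based host coordinate
       len = len, identity = ident)
}
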
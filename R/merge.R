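# Multi-k merge strategy: pool assemblies, remove redundancy by greedy
# longest-first clustering at an identity threshold (both strands), then
# meta-assemble overlapping contigs into consensus sequences.

#' Pool several assemblies into one
#'
#' Contig ids are prefixed with their source assembly label so pooled ids
#' are guaranteed unique; counts and total length add.
#'
#' @param assemblies list of [assembly_set] objects (>= 1).
#' @param label label of the pooled assembly.
#' @return an [assembly_set].
#' @export
pool_assemblies <- function(assemblies, label = "pooled") {
  stopifnot(length(assemblies) >= 1)
  labels <- make.unique(vapply(assemblies, function(a) a$label, ""))
  seqs <- unlist(lapply(seq_along(assemblies), function(i) {
    s <- assemblies[[i]]$seqs
    names(s) <- paste(labels[[i]], names(s), sep = ":")
    s
  }))
  assembly_set(seqs, label = label)
}

#' Pairwise sequence identity (end-gap-free, shorter as denominator)
#'
#' Identity is the maximum number of matching columns over every gap-free
#' placement of the shorter sequence inside the longer one, divided by the
#' length of the shorter sequence (the convention of greedy clustering
#' tools).  With `both_strands = TRUE` the reverse complement of `b` is also
#' considered and the maximum taken.
#'
#' @param a,b DNA sequences (character scalars).
#' @param both_strands compare `b` on both strands, default TRUE.
#' @return identity fraction in `[0, 1]`.
#' @examples
#' sequence_identity("ACGTACGT", "ACGTACGT")            # 1
#' sequence_identity("ACGT", "TTACGTTT")                # 1 (contained)
#' @export
sequence_identity <- function(a, b, both_strands = TRUE) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  cands <- if (both_strands) c(b, revcomp(b)) else b
  best <- 0L
  ar <- charToRaw(a)
  ns <- length(ar)
  for (s in cands) {
    br <- charToRaw(s)
    for (off in 0:(length(br) - ns)) {
      m <- sum(ar == br[(off + 1L):(off + ns)])
      if (m > best) best <- m
    }
  }
  best / ns
}

# Exact decision "identity >= threshold?" with a pigeonhole accelerator:
# an alignment with at most k mismatches must contain one of k+1 equal
# blocks of the shorter sequence verbatim, so candidate offsets come from
# exact block matches.  Falls back to the exhaustive scan for very short
# sequences or permissive thresholds.
identity_at_least <- function(shorter, longer, threshold, both_strands = TRUE) {
  ns <- nchar(shorter)
  nl <- nchar(longer)
  max_mm <- floor((1 - threshold) * ns)
  blocks <- max_mm + 1L
  blen <- ns %/% blocks
  if (blen < 8L)
    return(sequence_identity(shorter, longer, both_strands) >= threshold)
  ar <- charToRaw(shorter)
  for (tmpl in if (both_strands) c(longer, revcomp(longer)) else longer) {
    br <- charToRaw(tmpl)
    offs <- integer(0)
    for (b in seq_len(blocks)) {
      p <- (b - 1L) * blen + 1L
      block <- substr(shorter, p, p + blen - 1L)
      hit <- gregexpr(block, tmpl, fixed = TRUE)[[1]]
      if (hit[[1]] != -1L) offs <- c(offs, hit - p)
    }
    offs <- unique(offs[offs >= 0L & offs <= nl - ns])
    for (off in offs) {
      if (sum(ar == br[(off + 1L):(off + ns)]) / ns >= threshold)
        return(TRUE)
    }
  }
  FALSE
}

#' Greedy longest-first clustering at an identity threshold
#'
#' Sequences are sorted by length descending (ties keep input order); each
#' sequence joins the first existing cluster whose representative it matches
#' at or above the identity threshold (identity over the shorter sequence,
#' both strands by default), otherwise it founds a new cluster.  Cluster
#' representatives are therefore always the longest member.
#'
#' @param assembly an [assembly_set].
#' @param identity_threshold identity in (0, 1], default 0.99.
#' @param both_strands compare both strands, default TRUE.
#' @return list with `representatives` (an [assembly_set], founding order)
#'   and `clusters` (data frame: representative, member, identity; one row
#'   per non-representative member).
#' @export
cluster_reduce <- function(assembly, identity_threshold = 0.99,
                           both_strands = TRUE) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  seqs <- assembly$seqs
  ord <- order(-nchar(seqs), seq_along(seqs))
  reps <- integer(0)                 # indices into seqs, founding order
  member_rows <- list()
  for (i in ord) {
    joined <- FALSE
    for (r in reps) {
      if (identity_at_least(seqs[[i]], seqs[[r]], identity_threshold,
                            both_strands)) {
        member_rows[[length(member_rows) + 1L]] <- data.frame(
          representative = names(seqs)[[r]], member = names(seqs)[[i]],
          identity = sequence_identity(seqs[[i]], seqs[[r]], both_strands),
          stringsAsFactors = FALSE)
        joined <- TRUE
        break
      }
    }
    if (!joined) reps <- c(reps, i)
  }
  clusters <- if (length(member_rows)) do.call(rbind, member_rows) else
    data.frame(representative = character(0), member = character(0),
               identity = numeric(0), stringsAsFactors = FALSE)
  list(representatives = assembly_set(seqs[reps],
                                      label = paste0(assembly$label, "_nr")),
       clusters = clusters)
}

# Longest suffix(a)-prefix(b) overlap of length >= min_overlap with identity
# >= min_identity; returns 0 when none qualifies.
best_suffix_prefix <- function(a, b, min_overlap, min_identity) {
  ar <- charToRaw(a)
  br <- charToRaw(b)
  la <- length(ar)
  kmax <- min(la, length(br))
  if (kmax < min_overlap) return(0L)
  for (k in kmax:min_overlap) {
    mm <- k - sum(ar[(la - k + 1L):la] == br[1:k])
    if (mm <= floor((1 - min_identity) * k)) return(k)
  }
  0L
}

#' Greedy overlap meta-assembly into consensus sequences
#'
#' Repeatedly finds the pair of sequences with the longest suffix-prefix
#' overlap of at least `min_overlap` bases at identity >=
#' `min_overlap_identity` (considering both strands of the second sequence)
#' and replaces the pair with their consensus; disagreements inside the
#' overlap take the base from the longer parent.  Terminates when no
#' qualifying overlap remains.  Inputs merged with nothing become
#' singletons.
#'
#' @param assembly an [assembly_set] (typically clustering output).
#' @param min_overlap minimum overlap length in bases, default 40.
#' @param min_overlap_identity minimum overlap identity, default 0.90.
#' @return list of class `meta_assembly_result`: `contigs` (consensus
#'   sequences built from >= 2 inputs), `singletons` (unmerged inputs),
#'   `members` (named list: output id -> input ids).
#' @export
meta_assemble <- function(assembly, min_overlap = 40L,
                          min_overlap_identity = 0.90) {
  stopifnot(min_overlap >= 1, min_overlap_identity > 0,
            min_overlap_identity <= 1)
  seqs <- as.list(assembly$seqs)
  members <- as.list(contig_ids(assembly))
  merged_flag <- rep(FALSE, length(seqs))
  names(members) <- names(seqs)
  pair_best <- function(i, j) {
    # best (k, orientation) for suffix(i) -> prefix(j)
    k_f <- best_suffix_prefix(seqs[[i]], seqs[[j]], min_overlap,
                              min_overlap_identity)
    k_r <- best_suffix_prefix(seqs[[i]], revcomp(seqs[[j]]), min_overlap,
                              min_overlap_identity)
    if (k_f >= k_r) c(k = k_f, rc = 0L) else c(k = k_r, rc = 1L)
  }
  n <- length(seqs)
  K <- matrix(0L, n, n)
  RC <- matrix(0L, n, n)
  if (n >= 2) {
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
      pb <- pair_best(i, j)
      K[i, j] <- pb[["k"]]
      RC[i, j] <- pb[["rc"]]
    }
  }
  alive <- rep(TRUE, length(seqs))
  repeat {
    idx <- which(alive)
    if (length(idx) < 2) break
    sub <- K[idx, idx, drop = FALSE]
    if (max(sub) == 0L) break
    w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    i <- idx[[w[[1]]]]
    j <- idx[[w[[2]]]]
    k <- K[i, j]
    b <- if (RC[i, j] == 1L) revcomp(seqs[[j]]) else seqs[[j]]
    a <- seqs[[i]]
    la <- nchar(a)
    lb <- nchar(b)
    cons <- if (lb > la)
      paste0(substr(a, 1L, la - k), b)           # overlap bases from b
    else
      paste0(a, substr(b, k + 1L, lb))           # overlap bases from a
    new_i <- length(seqs) + 1L
    seqs[[new_i]] <- cons
    members[[new_i]] <- c(members[[i]], members[[j]])
    merged_flag[[new_i]] <- TRUE
    alive[c(i, j)] <- FALSE
    alive[[new_i]] <- TRUE
    # grow the overlap cache for the new sequence
    K <- rbind(cbind(K, 0L), 0L)
    RC <- rbind(cbind(RC, 0L), 0L)
    for (t in which(alive)) if (t != new_i) {
      pb <- pair_best(new_i, t)
      K[new_i, t] <- pb[["k"]]
      RC[new_i, t] <- pb[["rc"]]
      pb <- pair_best(t, new_i)
      K[t, new_i] <- pb[["k"]]
      RC[t, new_i] <- pb[["rc"]]
    }
  }
  idx <- which(alive)
  is_contig <- merged_flag[idx]
  mk <- function(ii, tag) {
    s <- unlist(seqs[ii])
    if (is.null(s)) s <- character(0)
    names(s) <- if (length(ii)) sprintf("%s%03d", tag, seq_along(ii)) else
      character(0)
    s
  }
  contig_seqs <- mk(idx[is_contig], "meta_contig")
  singleton_idx <- idx[!is_contig]
  singleton_seqs <- unlist(seqs[singleton_idx])
  if (is.null(singleton_seqs)) singleton_seqs <- character(0)
  names(singleton_seqs) <- unlist(members[singleton_idx])
  mem <- members[idx]
  names(mem)[is_contig] <- names(contig_seqs)
  names(mem)[!is_contig] <- names(singleton_seqs)
  structure(list(contigs = assembly_set(contig_seqs, label = "meta_contigs"),
                 singletons = assembly_set(singleton_seqs,
                                           label = "meta_singletons"),
                 members = mem),
            class = "meta_assembly_result")
}

#' Pool meta-assembly contigs and singletons into a final assembly
#'
#' @param result a `meta_assembly_result` from [meta_assemble()].
#' @param tag id prefix for the final assembly, default "merged".
#' @return an [assembly_set]: consensus contigs first, then singletons,
#'   relabelled `tag_1`, `tag_2`, ...
#' @export
finalize_merge <- function(result, tag = "merged") {
  seqs <- c(result$contigs$seqs, result$singletons$seqs)
  if (length(seqs))
    names(seqs) <- sprintf("%s_%d", tag, seq_along(seqs))
  assembly_set(seqs, label = tag)
}

#' Full multi-k merge pipeline
#'
#' Pool -> cluster at the identity threshold -> meta-assemble overlaps ->
#' pool contigs with singletons -> length filter.
#'
#' @param assemblies list of [assembly_set] objects.
#' @param identity_threshold clustering identity, default 0.99.
#' @param both_strands cluster on both strands, default TRUE.
#' @param min_overlap,min_overlap_identity meta-assembly overlap rule,
#'   defaults 40 bases at 0.90.
#' @param min_len final length filter in bases, default 300.
#' @param tag label/id prefix of the merged assembly.
#' @return an [assembly_set].
#' @export
merge_assemblies <- function(assemblies, identity_threshold = 0.99,
                             both_strands = TRUE, min_overlap = 40L,
                             min_overlap_identity = 0.90, min_len = 300L,
                             tag = "merged") {
  pooled <- pool_assemblies(assemblies)
  nr <- cluster_reduce(pooled, identity_threshold, both_strands)
  meta <- meta_assemble(nr$representatives, min_overlap, min_overlap_identity)
  filter_contigs(finalize_merge(meta, tag = tag), min_len = min_len)
}
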
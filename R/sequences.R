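#' Domain scheme for sequence design
#'
#' Signal strands use a three-letter code (A, T and C only), which is
#' sufficient to eliminate undesired interactions between signal strands in
#' the seesaw architecture; complements (gate bottom strands) then contain
#' G. One universal toehold is shared by all nodes, and every node carries
#' its own branch-migration domain.
#'
#' @param bm_len Branch-migration domain length (nt).
#' @param toe_len Toehold length (nt).
#' @param max_run Maximum allowed homopolymer run length (a run of
#'   `max_run` identical bases is a violation).
#' @param min_hamming Minimum pairwise Hamming distance between
#'   branch-migration domains.
#' @param toehold Optional fixed toehold sequence (generated from the seed
#'   otherwise).
#' @return A `domain_scheme` list.
#' @export
domain_scheme <- function(bm_len = 15, toe_len = 5, max_run = 4,
                          min_hamming = 6, toehold = NULL) {
  stopifnot(bm_len > 0, toe_len > 0, max_run >= 2, min_hamming >= 0)
  structure(list(bm_len = bm_len, toe_len = toe_len, max_run = max_run,
                 min_hamming = min_hamming, toehold = toehold,
                 alphabet = c("A", "C", "T")),
            class = "domain_scheme")
}

has_long_run <- function(seq, max_run) {
  grepl(sprintf("(.)\\1{%d,}", max_run - 1), seq)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

random_domain <- function(len, alphabet, max_run) {
  repeat {
    b <- sample(alphabet, len, replace = TRUE)
    s <- paste(b, collapse = "")
    if (has_long_run(s, max_run)) next
    # single-base runs at both ends keep any domain junction run-safe
    if (len >= 2 && (b[1] == b[2] || b[len] == b[len - 1])) next
    return(s)
  }
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Design DNA sequences for every species of a compiled circuit
#'
#' Generates one universal toehold and a distinct branch-migration domain
#' per node (three-letter code, homopolymer-run and pairwise Hamming
#' constraints enforced by construction), then assembles strands: a signal
#' strand from node j to node i is `BM(j) + toehold + BM(i)` (5'->3');
#' gate:output and bound-gate complexes add the node's 25-nt base strand
#' (toehold* + BM* + toehold*); thresholds are a 25-nt bottom strand with
#' extended toehold plus a 15-nt top strand; reporters use a 20-nt bottom
#' and 15-nt fluorophore-bearing top strand.
#'
#' @param circuit A `seesaw_circuit`.
#' @param seed Integer seed; the same seed and circuit always yield the
#'   same sequences.
#' @param scheme A [domain_scheme()].
#' @param max_tries Attempts per domain before giving up on the
#'   distance constraint.
#' @return Data frame (species, strand role, 5'->3' sequence, length).
#' @export
design_sequences <- function(circuit, seed = 1, scheme = domain_scheme(),
                             max_tries = 10000) {
  stopifnot(inherits(circuit, "seesaw_circuit"))
  withr::with_seed(seed, {
    toe <- scheme$toehold
    if (is.null(toe)) toe <- random_domain(scheme$toe_len, scheme$alphabet,
                                           scheme$max_run)
    node_ids <- sort(circuit$nodes$id)
    bm <- setNames(character(length(node_ids)), node_ids)
    for (i in seq_along(node_ids)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- random_domain(scheme$bm_len, scheme$alphabet, scheme$max_run)
        prev <- bm[seq_len(i - 1)]
        if (all(vapply(prev, function(p) hamming(p, cand) >= scheme$min_hamming,
                       logical(1)))) {
          bm[i] <- cand; ok <- TRUE; break
        }
      }
      if (!ok) stop("domain-uniqueness constraint unsatisfiable at length ",
                    scheme$bm_len)
    }

    signal_seq <- function(j, i) paste0(bm[[as.character(j)]], toe,
                                        bm[[as.character(i)]])
    base_seq <- function(i) revcomp(paste0(toe, bm[[as.character(i)]], toe))
    rows <- list()
    add <- function(species, strand, seq) {
      rows[[length(rows) + 1]] <<- data.frame(species = species,
                                              strand = strand, sequence = seq,
                                              length = nchar(seq))
    }
    wire_ends <- function(id) as.integer(strsplit(id, "_")[[1]][2:3])

    for (i in seq_len(nrow(circuit$species))) {
      s <- circuit$species[i, ]
      if (s$role %in% c("input", "fuel")) {
        e <- wire_ends(s$id)
        add(s$id, "single", signal_seq(e[1], e[2]))
      } else if (s$role == "gate_output") {
        e <- wire_ends(sub("^g", "w", s$id))
        add(s$id, "top", signal_seq(e[1], e[2]))
        add(s$id, "bottom", base_seq(e[1]))
      } else if (s$role == "threshold") {
        e <- wire_ends(sub("^th", "w", s$id))
        j <- e[1]; nd <- e[2]
        bmj <- bm[[as.character(j)]]
        ext <- substr(bmj, nchar(bmj) - scheme$toe_len + 1, nchar(bmj))
        add(s$id, "bottom", revcomp(paste0(ext, toe, bm[[as.character(nd)]])))
        add(s$id, "top", bm[[as.character(nd)]])
      } else if (s$role == "reporter") {
        r <- as.integer(sub("^rep_", "", s$id))
        add(s$id, "bottom", revcomp(paste0(toe, bm[[as.character(r)]])))
        add(s$id, "top", bm[[as.character(r)]])
      }
    }
    seqs <- do.call(rbind, rows)
    attr(seqs, "toehold") <- toe
    attr(seqs, "bm_domains") <- bm
    seqs
  })
}

#' Validate designed sequences against the string constraints
#'
#' Report-only checks: signal strands (single-stranded species) restricted
#' to the three-letter {A, C, T} alphabet; no homopolymer run of
#' `max_run` or more anywhere; pairwise Hamming distance between
#' branch-migration domains at or above the floor.
#'
#' @param seqs Output of [design_sequences()].
#' @param scheme The [domain_scheme()] the constraints come from.
#' @return Data frame of violations (species, check, detail); zero rows
#'   when everything passes.
#' @export
validate_sequences <- function(seqs, scheme = domain_scheme()) {
  viol <- list()
  flag <- function(species, check, detail) {
    viol[[length(viol) + 1]] <<- data.frame(species = species, check = check,
                                            detail = detail)
  }
  for (i in seq_len(nrow(seqs))) {
    s <- seqs[i, ]
    if (s$strand == "single" && grepl("[^ACT]", s$sequence))
      flag(s$species, "three_letter_code",
           sprintf("signal strand contains %s",
                   paste(unique(strsplit(gsub("[ACT]", "", s$sequence),
                                         "")[[1]]), collapse = ",")))
    if (has_long_run(s$sequence, scheme$max_run))
      flag(s$species, "homopolymer_run",
           sprintf("run of >= %d identical bases", scheme$max_run))
  }
  bm <- attr(seqs, "bm_domains")
  if (!is.null(bm) && length(bm) > 1) {
    for (i in seq_len(length(bm) - 1)) for (j in (i + 1):length(bm)) {
      d <- hamming(bm[[i]], bm[[j]])
      if (d < scheme$min_hamming)
        flag(paste0("bm_", names(bm)[i], "/bm_", names(bm)[j]),
             "hamming_distance", sprintf("distance %d < %d", d,
                                         scheme$min_hamming))
    }
  }
  if (length(viol)) do.call(rbind, viol) else
    data.frame(species = character(), check = character(),
               detail = character())
}

#' Write designed sequences as FASTA
#'
#' One record per strand, named `<species>|<strand role>`.
#'
#' @param seqs Output of [design_sequences()].
#' @param path Output FASTA path.
#' @export
write_sequences_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(setNames(seqs$sequence,
                                           paste(seqs$species, seqs$strand,
                                                 sep = "|")))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
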
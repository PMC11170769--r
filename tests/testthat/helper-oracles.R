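# Independent oracles and small random-instance builders used across the
# suite. Oracles deliberately avoid the package's own code paths: reverse
# complements go through Biostrings, scans are naive position-by-position
# loops, and set algebra is done on the planted construction directly.

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# naive Hamming scan over one strand of one sequence
naive_scan_strand <- function(pattern, seq, k) {
  m <- nchar(pattern); n <- nchar(seq)
  if (n < m) return(integer(0))
  pc <- strsplit(pattern, "")[[1]]
  sc <- strsplit(seq, "")[[1]]
  npos <- n - m + 1L
  mm <- integer(npos)
  for (j in seq_len(m)) {
    mm <- mm + (sc[j:(j + npos - 1L)] != pc[j])
  }
  mm
}

# full oracle: every window of every sequence, both strands, with 3' counts
naive_binding_sites <- function(primer, db, k, tail_3p = 5L) {
  m <- nchar(primer)
  win3 <- min(tail_3p, m)
  rows <- list()
  for (sid in names(db)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") primer else oracle_revcomp(primer)
      mm <- naive_scan_strand(pat, db[[sid]], k)
      hit <- which(mm <= k)
      for (s in hit) {
        site <- substr(db[[sid]], s, s + m - 1L)
        mm3 <- if (strand == "+") {
          sum(strsplit(substr(pat, m - win3 + 1L, m), "")[[1]] !=
                strsplit(substr(site, m - win3 + 1L, m), "")[[1]])
        } else {
          sum(strsplit(substr(pat, 1L, win3), "")[[1]] !=
                strsplit(substr(site, 1L, win3), "")[[1]])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = sid, start = s, end = s + m - 1L, strand = strand,
          mismatches = mm[s], mismatches_3p = mm3,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(seq_id = character(), start = integer(), end = integer(),
               strand = character(), mismatches = integer(),
               mismatches_3p = integer())
  out[order(out$seq_id, out$start, out$strand), , drop = FALSE]
}

# brute-force dimer score: enumerate every ungapped antiparallel offset
brute_dimer <- function(a, b, anchor_3p = FALSE) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(ac); m <- length(bc)
  best <- 0L
  for (d in (-(m - 1L)):(n - 1L)) {
    # a[i] pairs b[j] with j = d + m + 1 - i reversed layout
    i <- max(1L, d + 1L):min(n, d + m)
    if (anchor_3p && !(n %in% i)) next
    j <- m - (i - d) + 1L
    sc <- sum(ifelse(comp[ac[i]] == bc[j], 1L, -1L))
    best <- max(best, sc)
  }
  best
}

# brute-force hairpin: every (i, j) pairing start and every stem length
brute_hairpin <- function(s, min_loop = 3L) {
  sc <- strsplit(s, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(sc)
  best <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i - 1L < min_loop) next
      # stem extending outward from (i, j): pairs (i - t, j + t)
      score <- 0L
      t <- 0L
      while (i - t >= 1L && j + t <= n) {
        score <- score + (if (comp[sc[i - t]] == sc[j + t]) 1L else -1L)
        best <- max(best, score)
        t <- t + 1L
      }
    }
  }
  best
}

# random multi-isoform gene construction with a known junction incidence;
# returns GTF/FASTA text lines plus the planted truth
random_gene_spec <- function(gene_idx, rng_unused = NULL) {
  n_pool <- sample(4:12, 1L)
  n_iso <- sample(1:6, 1L)
  strand <- sample(c("+", "-"), 1L)
  exon_len <- 30L
  gap <- 20L
  starts <- 1000L + (seq_len(n_pool) - 1L) * (exon_len + gap)
  ends <- starts + exon_len - 1L
  gene_id <- sprintf("G%03d", gene_idx)
  chrom <- sprintf("c%03d", gene_idx)
  iso <- lapply(seq_len(n_iso), function(k) {
    sz <- sample(2:n_pool, 1L)
    sort(sample(seq_len(n_pool), sz))
  })
  # planted truth: junction (in transcription order) -> transcript ids
  jx <- list()
  for (k in seq_along(iso)) {
    sl <- iso[[k]]
    if (strand == "-") sl <- rev(sl)
    for (t in seq_len(length(sl) - 1L)) {
      up <- sl[t]; dn <- sl[t + 1L]
      key <- if (strand == "+") paste(ends[up], starts[dn], sep = "_") else
        paste(starts[up], ends[dn], sep = "_")
      jx[[key]] <- union(jx[[key]], sprintf("%s.T%d", gene_id, k))
    }
  }
  gtf <- character(0)
  for (k in seq_along(iso)) {
    for (sl in iso[[k]]) {
      gtf <- c(gtf, paste(chrom, "test", "exon", starts[sl], ends[sl], ".",
                          strand, ".",
                          sprintf('gene_id "%s"; transcript_id "%s.T%d";',
                                  gene_id, gene_id, k),
                          sep = "\t"))
    }
  }
  chrom_len <- max(ends) + 100L
  list(gene_id = gene_id, chrom = chrom, chrom_len = chrom_len,
       n_iso = n_iso, gtf = gtf, incidence = jx,
       tx_ids = sprintf("%s.T%d", gene_id, seq_len(n_iso)))
}

# write a batch of random genes as one GTF + one genome and load them
load_random_genes <- function(n_genes, seed) {
  set.seed(seed)
  specs <- lapply(seq_len(n_genes), random_gene_spec)
  gtf <- unlist(lapply(specs, `[[`, "gtf"))
  fa <- unlist(lapply(specs, function(sp) {
    c(sprintf(">%s", sp$chrom), random_dna_str(sp$chrom_len))
  }))
  d <- withr::local_tempdir(.local_envir = parent.frame())
  gtf_path <- file.path(d, "genes.gtf")
  fa_path <- file.path(d, "genome.fa")
  writeLines(gtf, gtf_path)
  writeLines(fa, fa_path)
  models <- read_gene_models(gtf_path, fa_path)
  list(specs = specs, models = models)
}

# brute-force perfect junction set from a planted incidence list
oracle_perfect_set <- function(incidence, all_tx, targets) {
  names(Filter(function(tx) {
    setequal(intersect(tx, targets), targets) &&
      length(intersect(tx, setdiff(all_tx, targets))) == 0L
  }, incidence))
}

# a friendly design template: GC-balanced flanks around a junction
friendly_template <- function(seed = 1L, left = 150L, right = 150L) {
  set.seed(seed)
  list(template = paste0(random_dna_str(left, 0.55), random_dna_str(right, 0.55)),
       junction = left)
}
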
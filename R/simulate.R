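#' Simulation configuration for the plastome evolution generator
#'
#' Defaults emulate the composition and mutation-process biases of small
#' angiosperm plastomes: GC content 0.39, roughly 53/11/33 percent
#' coding/intron/spacer, a transition-biased 12-class substitution spectrum
#' with depressed A<->T and G<->C transversion pools, deletion-biased
#' indels (8.5:1), insertion-biased tandem repeats (85:15), slippage-driven
#' microsatellite loci, and stem-loop inversions at planted inverted-repeat
#' substrates (stems 7-36 bp, loops 2-92 bp). Rates are per site per
#' million years; with the default dated topology (250.1 My of additive
#' ingroup time plus outgroup branches) a 20 kb genome accumulates on the
#' order of 1500 substitutions and some tens of events per structural
#' category.
#'
#' @param genome_length root genome length (bp).
#' @param frac_coding,frac_intron,frac_spacer partition fractions (sum 1).
#' @param gc GC content of generated sequence.
#' @param sub_rate substitution rate (events/site/My).
#' @param class_weights named weights over the 12 directed substitution
#'   classes (normalized internally).
#' @param indel_rate,repeat_rate,ms_rate,inv_rate structural event rates
#'   (events/site/My).
#' @param del_ins_odds deletion:insertion odds for indels.
#' @param indel_size_probs probabilities of the four indel size classes
#'   1-10, 11-50, 51-100, >100 bp (uniform within class; >100 spans
#'   101-364 bp).
#' @param repeat_gain_prob probability that a repeat event is a gain.
#' @param repeat_size_weights weights for repeat unit sizes 3..10 and >10
#'   (11-22 bp uniform).
#' @param ms_loci_per_kb,inv_substrates_per_kb planted locus densities.
#' @param ms_motif_probs probabilities of mono-A/T, mono-C/G, di-, tri-
#'   nucleotide microsatellite motifs.
#' @param stem_range,loop_range inversion substrate stem and loop lengths.
#' @param hotspot_multiplier,hotspot_fraction optional per-unit rate
#'   heterogeneity: a `hotspot_fraction` of annotation units gets all its
#'   rates multiplied by `hotspot_multiplier` (1 = homogeneous; used to
#'   create the structural/nucleotide co-localization scenario).
#' @param reference reference taxon name for annotation output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome_length = 20000L,
                       frac_coding = 0.53, frac_intron = 0.11,
                       frac_spacer = 0.33, gc = 0.39,
                       sub_rate = 2e-4,
                       class_weights = NULL,
                       indel_rate = 5.5e-6, del_ins_odds = 8.5,
                       indel_size_probs = c(0.758, 0.141, 0.056, 0.045),
                       repeat_rate = 3.6e-6, repeat_gain_prob = 0.853,
                       repeat_size_weights = c(4, 28, 52, 21, 2, 0, 3, 3, 4),
                       ms_rate = 4e-6, ms_loci_per_kb = 0.65,
                       ms_motif_probs = c(96, 13, 8, 2) / 119,
                       inv_rate = 4e-7, inv_substrates_per_kb = 0.65,
                       stem_range = c(7L, 36L), loop_range = c(2L, 92L),
                       hotspot_multiplier = 1, hotspot_fraction = 0.2,
                       reference = "Calycanthus_floridus") {
  if (is.null(class_weights)) {
    pools <- c("A->G+T->C" = 0.3085, "G->A+C->T" = 0.3085,
               "A->C+T->G" = 0.175, "C->A+G->T" = 0.143,
               "A->T+T->A" = 0.0284, "G->C+C->G" = 0.0365)
    class_weights <- setNames(pools[POOLED_OF[DIRECTED_CLASSES]] / 2,
                              DIRECTED_CLASSES)
  }
  fr <- c(frac_coding, frac_intron, frac_spacer)
  if (any(fr < 0) || sum(fr) <= 0)
    stop("partition fractions must be non-negative with a positive sum")
  fr <- fr / sum(fr)  # stated as proportions; normalized here
  frac_coding <- fr[1L]; frac_intron <- fr[2L]; frac_spacer <- fr[3L]
  stopifnot(all(c(sub_rate, indel_rate, repeat_rate, ms_rate, inv_rate) >= 0))
  structure(list(
    genome_length = as.integer(genome_length), frac_coding = frac_coding,
    frac_intron = frac_intron, frac_spacer = frac_spacer, gc = gc,
    sub_rate = sub_rate,
    class_weights = class_weights / sum(class_weights),
    indel_rate = indel_rate, del_ins_odds = del_ins_odds,
    indel_size_probs = indel_size_probs / sum(indel_size_probs),
    repeat_rate = repeat_rate, repeat_gain_prob = repeat_gain_prob,
    repeat_size_weights = repeat_size_weights / sum(repeat_size_weights),
    ms_rate = ms_rate, ms_loci_per_kb = ms_loci_per_kb,
    ms_motif_probs = ms_motif_probs / sum(ms_motif_probs),
    inv_rate = inv_rate, inv_substrates_per_kb = inv_substrates_per_kb,
    stem_range = as.integer(stem_range), loop_range = as.integer(loop_range),
    hotspot_multiplier = hotspot_multiplier,
    hotspot_fraction = hotspot_fraction,
    reference = reference), class = "sim_config")
}

rand_bases <- function(n, gc) {
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

STOPS <- c("TAA", "TAG", "TGA")

rand_codons <- function(n, gc) {
  out <- character(n)
  need <- seq_len(n)
  while (length(need)) {
    cand <- paste0(rand_bases(length(need), gc), rand_bases(length(need), gc),
                   rand_bases(length(need), gc))
    ok <- !cand %in% STOPS
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

GENE_PREFIXES <- c("atp", "ndh", "pet", "psa", "psb", "rpl", "rpo", "rps",
                   "ycf", "rbc", "mat", "ccs")

#' Generate an annotated plastome-like root sequence
#'
#' Lays out genes (ATG + stop-free codons + stop, a fraction carrying one
#' intron), introns and intergenic spacers at the configured fractions and
#' GC content, and plants microsatellite runs and inverted-repeat pairs in
#' spacers as substrates for the slippage and inversion processes.
#' Deterministic for a given (config, seed).
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list: `seq` (character vector of bases), `regions`
#'   (a [region_map()]), `ms_loci` (data.frame start/end/motif/period),
#'   `inv_substrates` (data.frame loop_start/loop_end/stem_length).
#' @export
generate_root <- function(config, seed) {
  set.seed(seed)
  L <- config$genome_length
  target_coding <- round(config$frac_coding * L)
  target_intron <- round(config$frac_intron * L)
  # plan genes
  genes <- list()
  coding <- 0L
  while (coding < target_coding - 600L) {
    ncod <- sample(100:450, 1L)
    genes[[length(genes) + 1L]] <- list(len = 3L * ncod)
    coding <- coding + 3L * ncod
  }
  ng <- length(genes)
  if (ng == 0L && target_coding >= 300L) {
    genes <- list(list(len = 3L * (target_coding %/% 3L)))
    ng <- 1L
  }
  prefixes <- sample(rep(GENE_PREFIXES, length.out = max(ng, 1L)))
  for (i in seq_len(ng)) {
    genes[[i]]$name <- paste0(prefixes[i], LETTERS[(i - 1L) %/% length(GENE_PREFIXES) + 1L],
                              i)
    genes[[i]]$strand <- sample(c("+", "-"), 1L, prob = c(0.7, 0.3))
    genes[[i]]$intron <- 0L
  }
  if (ng > 0L && target_intron > 0L) {
    n_int <- max(1L, round(ng * 0.25))
    holders <- sample(seq_len(ng), n_int)
    per <- as.integer(target_intron %/% n_int)
    for (i in holders) genes[[i]]$intron <- per
  }
  used <- sum(vapply(genes, function(g) g$len + g$intron, integer(1L)))
  spacer_total <- L - used
  if (spacer_total < ng + 1L) stop("partition fractions infeasible for genome length")
  cuts <- sort(sample(seq_len(max(spacer_total - 1L, 1L)), ng))
  spacer_lens <- diff(c(0L, cuts, spacer_total))
  # assemble
  seq_parts <- list(); rows <- list(); pos <- 0L
  add_spacer <- function(len) {
    if (len <= 0L) return(invisible())
    seq_parts[[length(seq_parts) + 1L]] <<- rand_bases(len, config$gc)
    rows[[length(rows) + 1L]] <<- data.frame(
      start = pos + 1L, end = pos + len, kind = "spacer",
      gene = NA_character_, strand = NA_character_, coding = FALSE)
    pos <<- pos + len
  }
  add_spacer(spacer_lens[1L])
  for (i in seq_len(ng)) {
    g <- genes[[i]]
    ncod <- g$len %/% 3L
    body <- rand_codons(ncod - 2L, config$gc)
    cds <- c("ATG", body, sample(STOPS, 1L))
    bases <- strsplit(paste(cds, collapse = ""), "")[[1L]]
    if (g$strand == "-")
      bases <- rev(unname(COMPLEMENT[bases]))
    if (g$intron > 0L) {
      # one intron between two exons, inserted mid-gene (codon boundary
      # irrelevant at the sequence level; phase bookkeeping is positional)
      cut <- 3L * sample(seq_len(ncod - 1L), 1L)
      ex1 <- bases[seq_len(cut)]; ex2 <- bases[(cut + 1L):length(bases)]
      ibases <- rand_bases(g$intron, config$gc)
      seq_parts[[length(seq_parts) + 1L]] <- c(ex1, ibases, ex2)
      rows[[length(rows) + 1L]] <- data.frame(
        start = pos + 1L, end = pos + cut, kind = "exon", gene = g$name,
        strand = g$strand, coding = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        start = pos + cut + 1L, end = pos + cut + g$intron, kind = "intron",
        gene = g$name, strand = g$strand, coding = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        start = pos + cut + g$intron + 1L, end = pos + cut + g$intron +
          length(ex2), kind = "exon", gene = g$name, strand = g$strand,
        coding = TRUE)
      pos <- pos + length(bases) + g$intron
    } else {
      seq_parts[[length(seq_parts) + 1L]] <- bases
      rows[[length(rows) + 1L]] <- data.frame(
        start = pos + 1L, end = pos + length(bases), kind = "exon",
        gene = g$name, strand = g$strand, coding = TRUE)
      pos <- pos + length(bases)
    }
    add_spacer(spacer_lens[i + 1L])
  }
  sq <- unlist(seq_parts, use.names = FALSE)
  regions <- region_map(do.call(rbind, rows), length(sq))
  # plant microsatellite runs and inverted-repeat substrates in spacers
  sp <- regions[regions$kind == "spacer", , drop = FALSE]
  claim <- cbind(start = integer(), end = integer())
  claim_free <- function(len, margin = 4L) {
    # a random spacer window of `len` bp not overlapping earlier claims
    for (try in 1:200) {
      r <- sp[sample(nrow(sp), 1L), ]
      if (r$end - r$start + 1L < len + 2L * margin) next
      s <- sample(seq(r$start + margin, r$end - margin - len + 1L), 1L)
      e <- s + len - 1L
      if (nrow(claim) == 0L || all(e < claim[, 1L] - margin |
                                     s > claim[, 2L] + margin)) {
        claim <<- rbind(claim, c(s, e))
        return(c(s, e))
      }
    }
    NULL
  }
  n_ms <- round(config$ms_loci_per_kb * length(sq) / 1000)
  ms <- list()
  for (i in seq_len(n_ms)) {
    type <- sample(4L, 1L, prob = config$ms_motif_probs)
    motif <- switch(type,
                    sample(c("A", "T"), 1L),
                    sample(c("C", "G"), 1L),
                    paste0(sample(c("A", "T"), 1L), sample(c("C", "G"), 1L)),
                    paste(sample(c("A", "C", "T"), 3L, replace = TRUE),
                          collapse = ""))
    copies <- switch(nchar(motif), sample(9:14, 1L), sample(4:7, 1L),
                     sample(4:5, 1L))
    runlen <- copies * nchar(motif)
    w <- claim_free(runlen)
    if (is.null(w)) next
    sq[w[1L]:w[2L]] <- strsplit(strrep(motif, copies), "")[[1L]]
    ms[[length(ms) + 1L]] <- data.frame(start = w[1L], end = w[2L],
                                        motif = motif,
                                        period = nchar(motif))
  }
  n_inv <- round(config$inv_substrates_per_kb * length(sq) / 1000)
  ivs <- list()
  for (i in seq_len(n_inv)) {
    stem <- sample(config$stem_range[1L]:config$stem_range[2L], 1L)
    loop <- sample(config$loop_range[1L]:config$loop_range[2L], 1L)
    w <- claim_free(2L * stem + loop, margin = 6L)
    if (is.null(w)) next
    stem_seq <- rand_bases(stem, config$gc)
    repeat {
      loop_seq <- rand_bases(loop, config$gc)
      if (!identical(loop_seq, rev(unname(COMPLEMENT[loop_seq])))) break
    }
    sq[w[1L]:w[2L]] <- c(stem_seq, loop_seq,
                         rev(unname(COMPLEMENT[stem_seq])))
    ivs[[length(ivs) + 1L]] <- data.frame(
      loop_start = w[1L] + stem, loop_end = w[1L] + stem + loop - 1L,
      stem_length = stem)
  }
  list(seq = sq, regions = regions,
       ms_loci = if (length(ms)) do.call(rbind, ms) else
         data.frame(start = integer(), end = integer(), motif = character(),
                    period = integer()),
       inv_substrates = if (length(ivs)) do.call(rbind, ivs) else
         data.frame(loop_start = integer(), loop_end = integer(),
                    stem_length = integer()))
}
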
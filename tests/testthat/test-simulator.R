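# independent replay of the truth log: maintain id -> base maps down the
# tree and re-derive every tip sequence from the log alone
replay_truth <- function(sim, topo = TOPO) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  root_map <- sim$root$seq
  names(root_map) <- as.character(seq_along(root_map))
  by_branch <- split(sim$truth, sim$truth$branch)
  tips <- list()
  walk <- function(node, map) {
    if (node != "root") {
      ev <- by_branch[[node]]
      for (i in seq_len(NROW(ev))) {
        ids <- strsplit(ev$ids[i], ",")[[1]]
        kind <- ev$kind[i]
        if (kind == "substitution") {
          stopifnot(identical(unname(map[ids]), ev$anc[i]))
          map[ids] <- ev$der[i]
        } else if (kind == "inversion") {
          map[ids] <- rev(unname(comp[map[ids]]))
        } else if (identical(ev$direction[i], "deletion")) {
          map <- map[setdiff(names(map), ids)]
        } else {  # insertion: place new ids; order within map is irrelevant
          seg <- strsplit(ev$segment[i], "")[[1]]
          map[ids] <- seg
        }
      }
    }
    if (node %in% topo$tips) { tips[[node]] <<- map; return(invisible()) }
    for (ch in topo$children[[node]]) walk(ch, map)
  }
  walk("root", root_map)
  tips
}

test_that("identical config and seed give byte-identical outputs", {
  s1 <- simulate_plastomes(sim_config(genome_length = 6000L), seed = 3)
  s2 <- simulate_plastomes(sim_config(genome_length = 6000L), seed = 3)
  expect_identical(s1$aln$mat, s2$aln$mat)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_plastomes(sim_config(genome_length = 6000L), seed = 4)
  expect_false(identical(s1$aln$mat, s3$aln$mat))
})

test_that("root genomes hit the configured composition", {
  root <- generate_root(sim_config(genome_length = 20000L, gc = 0.39), 17)
  gc <- mean(root$seq %in% c("G", "C"))
  expect_lt(abs(gc - 0.39), 0.02)
  lens <- tapply(root$regions$end - root$regions$start + 1L,
                 root$regions$kind, sum)
  expect_lt(abs(lens[["exon"]] / length(root$seq) - 0.548), 0.08)
  # per-gene exon sums are codon-complete
  expect_s3_class(root$regions, "region_map")
  # coding fraction 0: a single all-spacer genome
  r0 <- generate_root(sim_config(genome_length = 3000L, frac_coding = 0,
                                 frac_intron = 0, frac_spacer = 1), 17)
  expect_true(all(r0$regions$kind == "spacer"))
})

test_that("replaying the truth log reproduces every tip sequence", {
  sim <- simulate_plastomes(sim_config(genome_length = 6000L), seed = 19)
  tips <- replay_truth(sim)
  for (tx in TAXA) {
    map <- tips[[tx]]
    row <- rep("-", length(sim$master))
    row[match(as.integer(names(map)), sim$master)] <- unname(map)
    expect_identical(row, unname(sim$aln$mat[tx, ]), label = tx)
  }
})

test_that("with structural rates zero the SNP census matches the replayed truth", {
  cfg <- sim_config(genome_length = 6000L, indel_rate = 0, repeat_rate = 0,
                    ms_rate = 0, inv_rate = 0)
  sim <- simulate_plastomes(cfg, seed = 23)
  expect_false(any(sim$aln$mat == "-"))
  tips <- replay_truth(sim)
  ing <- do.call(rbind, lapply(ING, function(tx) unname(tips[[tx]])))
  truth_poly <- which(apply(ing, 2, function(z) length(unique(z)) > 1))
  called <- call_polymorphic_sites(sim$aln, TOPO)
  expect_identical(called$column, truth_poly)
})

test_that("with substitution rate zero tips differ only structurally", {
  cfg <- sim_config(genome_length = 6000L, sub_rate = 0, inv_rate = 0)
  sim <- simulate_plastomes(cfg, seed = 29)
  expect_equal(nrow(call_polymorphic_sites(sim$aln, TOPO)), 0L)
  expect_true(any(sim$aln$mat == "-"))
})

test_that("recovery scoring is exact on constructed cases", {
  truth <- data.frame(
    branch = "Idiospermum_australiense", kind = c("indel", "repeat"),
    direction = "deletion", ids = "1", anc = NA, der = NA, segment = NA,
    start_col = c(100L, 300L), end_col = c(110L, 306L),
    rank = "subfamily", carriers = "Idiospermum_australiense",
    stringsAsFactors = FALSE)
  calls <- data.frame(
    category = c("indel", "repeat"), start_col = c(100L, 300L),
    end_col = c(110L, 306L), rank = "subfamily",
    direction = "deletion", stringsAsFactors = FALSE)
  sc <- score_recovery(truth, data.frame(column = integer(),
                                         direction_known = logical(),
                                         rank = character(),
                                         parallel = logical(),
                                         ancestral = character()), calls)
  expect_true(all(sc$by_category$precision[1:2] == 1))
  expect_true(all(sc$by_category$recall[1:2] == 1))
  expect_equal(sc$direction_accuracy, 1)
  # empty call set: zero recall, undefined precision
  sc0 <- score_recovery(truth, data.frame(column = integer(),
                                          direction_known = logical(),
                                          rank = character(),
                                          parallel = logical(),
                                          ancestral = character()),
                        calls[0, ])
  expect_equal(sc0$by_category$recall[1], 0)
  expect_true(is.na(sc0$by_category$precision[1]))
  # category-shuffled calls lose exactly the shuffled fraction
  calls2 <- calls
  calls2$category <- rev(calls2$category)
  sc2 <- score_recovery(truth, data.frame(column = integer(),
                                          direction_known = logical(),
                                          rank = character(),
                                          parallel = logical(),
                                          ancestral = character()), calls2)
  expect_equal(sc2$by_category$recall[1:2], c(0, 0))
})

test_that("simulated datasets round-trip through the standard file formats", {
  sim <- simulate_plastomes(sim_config(genome_length = 6000L), seed = 31)
  dir <- tempfile()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(unlist(paths))))
  aln <- read_alignment(paths$alignment, reference = sim$aln$reference)
  expect_identical(aln$mat, sim$aln$mat)
  topo <- read_dated_tree(paths$tree)
  expect_equal(additive_time(topo), 250.1)
  rm <- read_annotation(paths$annotation, attr(sim$regions, "ref_length"))
  expect_equal(rm$kind, sim$regions$kind)
})
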
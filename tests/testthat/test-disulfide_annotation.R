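bond_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(protein_id = r[[1]], cys_a = as.integer(r[[2]]),
               cys_b = as.character(r[[3]]), stringsAsFactors = FALSE)
  }))
}

test_that("merging unifies identical bonds and keeps distinct ones apart", {
  t1 <- bond_df(list("P1", 10, 50))
  t2 <- bond_df(list("P1", 10, 50))
  t3 <- bond_df(list("P1", 50, 10))  # orientation must not matter
  m <- merge_bond_sources(list(a = t1, b = t2, c = t3))
  expect_equal(nrow(m), 1)
  expect_equal(m$n_sources, 3)
  expect_equal(m$sources, "a;b;c")
  m2 <- merge_bond_sources(list(a = bond_df(list("P1", 10, 50),
                                            list("P1", 10, 90))))
  expect_equal(nrow(m2), 2)
})

test_that("merge reproduces brute-force set algebra on a known overlap fixture", {
  set.seed(11)
  universe <- expand.grid(protein_id = paste0("P", 1:8),
                          cys_a = c(5L, 20L, 40L), stringsAsFactors = FALSE)
  universe$cys_b <- as.character(universe$cys_a + 37L)
  pick <- function() universe[runif(nrow(universe)) < 0.5, ]
  srcs <- list(u = pick(), v = pick(), w = pick())
  m <- merge_bond_sources(srcs)
  key <- function(d) paste(d$protein_id, d$cys_a, d$cys_b)
  union_keys <- unique(unlist(lapply(srcs, key)))
  expect_equal(nrow(m), length(union_keys))
  # per-bond source counts match direct membership tests
  counts <- sapply(key(m), function(k) {
    sum(vapply(srcs, function(s) k %in% key(s), TRUE))
  })
  expect_equal(m$n_sources, unname(counts))
  # idempotent and order-independent
  m_rev <- merge_bond_sources(rev(srcs))
  expect_equal(m$n_sources[order(key(m))], m_rev$n_sources[order(key(m_rev))])
  expect_equal(nrow(merge_bond_sources(list(one = m[1:3, 1:3]))), 3)
})

test_that("malformed residue indices are skipped with a warning", {
  bad <- data.frame(protein_id = c("P1", "P2"), cys_a = c("10", "oops"),
                    cys_b = c("50", "60"), stringsAsFactors = FALSE)
  expect_warning(m <- merge_bond_sources(list(src = bad)), "malformed")
  expect_equal(m$protein_id, "P1")
})

test_that("bond counting collapses alternative partners and halves self-pairings", {
  alt <- merge_bond_sources(list(s = bond_df(list("P1", 10, 50),
                                             list("P1", 10, 90))))
  expect_equal(count_protein_disulfides(alt), 1.0)
  self <- merge_bond_sources(list(s = bond_df(list("P1", 10, "SELF"))))
  expect_equal(count_protein_disulfides(self), 0.5)
  disjoint <- merge_bond_sources(list(s = bond_df(list("P1", 10, 50),
                                                  list("P1", 60, 90))))
  expect_equal(count_protein_disulfides(disjoint), 2.0)
  inter <- merge_bond_sources(list(s = bond_df(list("P1", 10, "OTHER"))))
  expect_equal(count_protein_disulfides(inter), 0)
  # a chain shares cysteine 50: only one bond can form at a time
  chain <- merge_bond_sources(list(s = bond_df(list("P1", 10, 50),
                                               list("P1", 50, 90))))
  expect_equal(count_protein_disulfides(chain), 1.0)
  expect_error(count_protein_disulfides(
    merge_bond_sources(list(s = bond_df(list("P1", 1, 2), list("P2", 1, 2))))),
    "single protein")
})

test_that("potential disulfides are floor(cysteines / 2)", {
  expect_equal(max_potential_disulfides("CACACACAC"), 2L)  # 5 cysteines
  expect_equal(max_potential_disulfides("MKLVNA"), 0L)
  expect_equal(max_potential_disulfides("CCCC"), 2L)
  expect_error(max_potential_disulfides("MKX9"), "non-amino-acid")
})

test_that("difficulty classification follows the cysteine layout", {
  b <- function(a, bb) data.frame(cys_a = a, cys_b = bb, partner = "cys")
  expect_equal(classify_difficulty(c(10, 50), b(10, 50))$protein, "cat1")
  expect_equal(classify_difficulty(c(10, 50, 90), b(10, 50))$protein, "cat2")
  expect_equal(classify_difficulty(c(10, 50, 90), b(10, 90))$protein, "cat3")
  inter <- data.frame(cys_a = 10, cys_b = NA, partner = "self")
  expect_equal(classify_difficulty(c(10, 50), inter)$protein, "cat4")
  # hardest intramolecular category wins for the protein
  two <- rbind(b(10, 50), b(50, 200))
  expect_equal(classify_difficulty(c(10, 50, 90, 200), two)$per_bond,
               c("cat2", "cat3"))
  expect_equal(classify_difficulty(c(10, 50, 90, 200), two)$protein, "cat3")
  expect_error(classify_difficulty(c(10, 50), b(10, 77)), "missing from")
  # every bond lands in exactly one category
  set.seed(3)
  for (i in 1:20) {
    cys <- sort(sample(1:300, sample(2:6, 1)))
    pair <- sort(sample(cys, 2))
    cls <- classify_difficulty(cys, b(pair[1], pair[2]))
    expect_true(cls$per_bond %in% c("cat1", "cat2", "cat3"))
  }
})

test_that("periplasmic restriction keeps only qualifying locations", {
  prof <- data.frame(protein_id = paste0("P", 1:6), n_cys = 2, bond_count = 1,
                     category = "cat1",
                     location = c("secreted", "cytoplasmic", "secreted outer membrane",
                                  "inner membrane", "secreted", NA),
                     stringsAsFactors = FALSE)
  kept <- periplasmic_subset(prof)
  expect_equal(kept$protein_id, c("P1", "P3", "P5"))
  expect_warning(kept2 <- periplasmic_subset(prof, on_missing = "keep"),
                 "lack location")
  expect_equal(kept2$protein_id, c("P1", "P3", "P5", "P6"))
  all_sec <- prof[prof$location %in% "secreted", ]
  expect_equal(periplasmic_subset(all_sec)$protein_id, all_sec$protein_id)
  # brute-force filter oracle
  expect_equal(nrow(kept),
               sum(prof$location %in% c("secreted", "secreted outer membrane")))
})

test_that("confidence filtering is a nested threshold family", {
  set.seed(5)
  srcs <- lapply(1:3, function(i) {
    bond_df(list("P1", 10, 50), list("P2", 5, 25), list("P3", 7, 70))[
      sample(c(TRUE, FALSE, TRUE)), ]
  })
  names(srcs) <- c("a", "b", "c")
  m <- merge_bond_sources(srcs)
  expect_equal(confidence_filter(m, 1), m)
  for (k in 1:2) {
    expect_true(all(confidence_filter(m, k + 1)$n_sources %in%
                      confidence_filter(m, k)$n_sources))
    expect_lte(nrow(confidence_filter(m, k + 1)), nrow(confidence_filter(m, k)))
  }
  fixed <- merge_bond_sources(list(
    a = bond_df(list("P1", 1, 9), list("P2", 1, 9), list("P3", 1, 9)),
    b = bond_df(list("P2", 1, 9), list("P3", 1, 9)),
    c = bond_df(list("P3", 1, 9))))
  expect_equal(nrow(confidence_filter(fixed, 2)), 2)
})

test_that("folding demand weights bond counts by abundance and is linear", {
  prof <- data.frame(protein_id = c("A", "B", "C"), n_cys = c(2, 4, 3),
                     bond_count = c(1, 2, 1),
                     category = c("cat1", "cat2", "cat3"),
                     location = "secreted", stringsAsFactors = FALSE)
  prot <- quantitative_proteome("fix", 1.0, c(A = 100, B = 50, C = 10))
  d <- folding_demand(prof, prot)
  expect_s3_class(d, "folding_demand")
  expect_equal(demand_vector(d), c(cat1 = 100, cat2 = 100, cat3 = 10))
  # doubling all abundances doubles all totals
  prot2 <- quantitative_proteome("fix2", 1.0, prot$abundances * 2)
  expect_equal(demand_vector(folding_demand(prof, prot2)),
               2 * demand_vector(d))
  # proteins missing from the proteome contribute zero
  prot3 <- quantitative_proteome("fix3", 1.0, c(A = 100))
  expect_message(d3 <- folding_demand(prof, prot3), "not quantified")
  expect_equal(demand_vector(d3), c(cat1 = 100, cat2 = 0, cat3 = 0))
  # brute-force summation oracle on a random fixture
  set.seed(9)
  n <- 40
  prof_r <- data.frame(protein_id = paste0("R", 1:n), n_cys = 3,
                       bond_count = sample(c(0.5, 1, 1.5, 2), n, TRUE),
                       category = sample(c("cat1", "cat2", "cat3", "cat4"), n, TRUE),
                       location = "secreted", stringsAsFactors = FALSE)
  ab <- setNames(runif(n, 1, 1000), prof_r$protein_id)
  d_r <- folding_demand(prof_r, quantitative_proteome("r", 1.0, ab))
  for (cc in c("cat1", "cat2", "cat3", "cat4")) {
    idx <- prof_r$category == cc
    expect_equal(d_r$bonds_per_cell[d_r$category == cc],
                 sum(prof_r$bond_count[idx] * ab[idx]))
  }
})

test_that("profiles combine records, cysteine inventory and locations", {
  srcs <- list(
    a = bond_df(list("P1", 10, 50), list("P2", 10, 50)),
    b = bond_df(list("P1", 10, 50), list("P2", 10, 90)))
  cys <- data.frame(protein_id = c("P1", "P2"),
                    cys_positions = c("10,50", "10,50,90"),
                    stringsAsFactors = FALSE)
  loc <- data.frame(protein_id = c("P1", "P2"),
                    location = c("secreted", "cytoplasmic"),
                    stringsAsFactors = FALSE)
  prof <- disulfide_profiles(merge_bond_sources(srcs), cys, loc)
  expect_equal(prof$category[prof$protein_id == "P1"], "cat1")
  # P2: cys 10 pairs with alternative partners -> one bond, hardest is cat3
  expect_equal(prof$bond_count[prof$protein_id == "P2"], 1)
  expect_equal(prof$category[prof$protein_id == "P2"], "cat3")
  expect_equal(prof$location, c("secreted", "cytoplasmic"))
  expect_error(disulfide_profiles(merge_bond_sources(srcs), cys[1, ], loc),
               "missing for protein")
})

test_that("the wide per-source sheet reader reproduces list-based merging", {
  sheet <- data.frame(protein_id = c("P1", "P1", "P2"),
                      cys_a = c(10, 60, 5), cys_b = c(50, 90, 25),
                      curated = c(1, 1, 0), ms_a = c(1, 0, 1),
                      ms_b = c(0, 0, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- read_dsb_sheet(path)
  expect_equal(nrow(m), 3)
  expect_equal(sort(m$n_sources), c(1, 2, 2))
})
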
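toy_tax <- function() {
  data.frame(
    asv_id = paste0("a", 1:10),
    lineage = c(
      "Bacteria;Desulfobacterota;c;o;f;Desulfovibrio",
      "Bacteria;Desulfobacterota;c;o;f;",
      "Bacteria;Cyanobacteria;c;o;f;Nostoc",
      "Bacteria;Firmicutes;c;o;f;Bacillus",
      "Bacteria;Proteobacteria;c;o;f;Pseudomonas",
      "Bacteria;Proteobacteria;c;o;f;",
      "Archaea;Euryarchaeota;c;o;f;Methanobacterium",
      "Bacteria;Halanaerobiaeota;c;o;f;Halanaerobium",
      "Bacteria;Actinobacteriota;c;o;f;",
      "Bacteria;Bacteroidota;c;o;f;"),
    stringsAsFactors = FALSE)
}

toy_rules <- function() {
  function_rules(data.frame(
    pattern = c("phylum:Desulfobacterota", "phylum:Desulfobacterota",
                "phylum:Cyanobacteria", "genus:Nostoc",
                "phylum:Halanaerobiaeota", "phylum:Euryarchaeota"),
    group = c("sulfate_respiration", "iron_respiration",
              "phototrophy", "nitrogen_fixation",
              "cellulolysis", "dark_hydrogen_oxidation"),
    stringsAsFactors = FALSE))
}

test_that("rules parse and reject malformed input", {
  r <- toy_rules()
  expect_equal(sort(unique(r$rank)), c("genus", "phylum"))
  expect_error(function_rules(data.frame(pattern = "nolevel", group = "g")),
               "malformed")
  expect_error(function_rules(data.frame(pattern = "kingdom:X", group = "g")),
               "unknown rank")
  expect_error(function_rules(data.frame(pattern = character(0),
                                         group = character(0))), "empty")
})

test_that("counts flow to every matching group without cross-normalization", {
  tax <- toy_tax()
  m <- cm(matrix(0, 2, 10), asvs = tax$asv_id)
  m[, "a1"] <- c(5, 7); m[, "a2"] <- c(3, 1); m[, "a3"] <- c(2, 2)
  m[, "a5"] <- c(100, 100); m[, "a7"] <- c(4, 0)
  mp <- map_functions(m, tax, toy_rules())
  # Desulfobacterota ASVs a1+a2 feed both sulfate and iron respiration
  expect_equal(unname(mp$group_profile[, "sulfate_respiration"]), c(8, 8))
  expect_equal(unname(mp$group_profile[, "iron_respiration"]), c(8, 8))
  # genus rule and phylum rule both catch a3 once per group
  expect_equal(unname(mp$group_profile[, "nitrogen_fixation"]), c(2, 2))
  expect_equal(unname(mp$group_profile[, "phototrophy"]), c(2, 2))
  # assigned fraction: a1, a2, a3, a7 of 10 ASVs carry assignments; a8 has
  # zero counts but still matches cellulolysis
  expect_equal(mp$assigned_asv_fraction, 5 / 10)
  expect_true(all(c("a1", "a2", "a3", "a7", "a8") %in% mp$assignments$asv_id))
  # multi-assignment: a1 appears in two groups
  expect_equal(sort(mp$assignments$group[mp$assignments$asv_id == "a1"]),
               c("iron_respiration", "sulfate_respiration"))
})

test_that("attribution percentages close to 100 per group", {
  tax <- toy_tax()
  m <- cm(matrix(0, 1, 10), asvs = tax$asv_id)
  m[, "a1"] <- 90; m[, "a2"] <- 10   # same phylum
  m[, "a3"] <- 50; m[, "a7"] <- 30; m[, "a8"] <- 20
  rules <- function_rules(data.frame(
    pattern = c("phylum:Desulfobacterota", "phylum:Cyanobacteria",
                "phylum:Euryarchaeota", "phylum:Halanaerobiaeota"),
    group = c("g1", "mixed", "mixed", "mixed")))
  mp <- map_functions(m, tax, rules)
  at <- function_attribution(m, mp, tax, "phylum")
  g1 <- at[at$group == "g1", ]
  expect_equal(g1$percent[g1$taxon == "Desulfobacterota"], 100)
  mixed <- at[at$group == "mixed", ]
  expect_equal(sum(mixed$percent), 100)
  expect_equal(sort(mixed$percent), c(20, 30, 50))

  # zero-read group flagged
  m0 <- m; m0[, c("a3", "a7", "a8")] <- 0
  mp0 <- map_functions(m0, tax, rules)
  at0 <- function_attribution(m0, mp0, tax, "phylum")
  expect_true(all(is.na(at0$percent[at0$group == "mixed"])))
})

test_that("the packaged miniature rules file loads and maps", {
  rules <- read_function_rules(system.file("extdata", "function_rules.tsv",
                                           package = "microdepth"))
  expect_true(all(c("sulfate_respiration", "phototrophy", "cellulolysis",
                    "dark_hydrogen_oxidation", "nitrogen_fixation") %in%
                    rules$group))
  ds <- simulate_dataset(simulation_params(n_plots = 2, n_times = 2,
                                           n_asvs = 300, library_size = 5000,
                                           seed = 8))
  mp <- map_functions(ds$counts, ds$taxonomy, rules)
  expect_gt(mp$assigned_asv_fraction, 0)
  expect_lt(mp$assigned_asv_fraction, 1)
  # group profiles are reproducible from the emitted assignment list
  for (g in colnames(mp$group_profile)) {
    members <- mp$assignments$asv_id[mp$assignments$group == g]
    manual <- if (length(members))
      rowSums(ds$counts[, members, drop = FALSE]) else rep(0, nrow(ds$counts))
    expect_equal(unname(mp$group_profile[, g]), unname(manual))
  }
})
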
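# Node I/O, atlas assignment, count aggregation and derived fractions.

test_that("node sets round-trip through nml and csv", {
  dir <- withr::local_tempdir()
  # empty set
  f0 <- file.path(dir, "empty.nml")
  write_nodes(node_set(), f0)
  expect_equal(nrow(read_nodes(f0)), 0)
  # hand-written three-node file
  nml <- '<things><thing id="1"><nodes>
    <node id="1" x="10.5" y="20" z="30" radius="1"/>
    <node id="2" x="1" y="2" z="3" radius="1"/>
    <node id="3" x="7" y="8" z="9" radius="1"/>
    </nodes><edges/></thing>
    <comments>
    <comment node="1" content="class=neuron;channel=green"/>
    <comment node="2" content="class=glia;channel=both;note=faint"/>
    </comments></things>'
  f1 <- file.path(dir, "hand.nml")
  writeLines(nml, f1)
  expect_warning(nd <- read_nodes(f1), "without a class tag")
  expect_equal(nd$id, 1:3)
  expect_equal(nd$x_um, c(10.5, 1, 7))
  expect_equal(nd$class[1:2], c("neuron", "glia"))
  expect_true(is.na(nd$class[3]))
  expect_equal(nd$channel[2], "both")
  expect_equal(nd$extra[2], "note=faint")   # unknown tags preserved
  # csv -> nml -> csv on the fixture is field-identical
  fx <- table2_fixture()
  sub <- node_set(as.data.frame(fx)[seq(1, nrow(fx), by = 37), ])
  fc <- file.path(dir, "a.csv"); fn <- file.path(dir, "a.nml")
  write_nodes(sub, fc)
  write_nodes(read_nodes(fc), fn)
  back <- read_nodes(fn)
  expect_equal(as.data.frame(back), as.data.frame(sub),
               ignore_attr = TRUE)
  # malformed file gives a context-carrying error
  f2 <- file.path(dir, "bad.nml")
  writeLines("<things><node id='1' x='nope'", f2)
  expect_error(read_nodes(f2), "malformed")
})

test_that("region assignment is voxel-containment with floor indexing", {
  atlas <- toy_atlas()
  # node at the centre of a labelled voxel
  vox <- which(atlas$labels == 7L, arr.ind = TRUE)[1, ]
  nd <- node_set(data.frame(id = 1L, x_um = (vox[3] - 0.5) * 10,
                            y_um = (vox[2] - 0.5) * 10,
                            z_um = (vox[1] - 0.5) * 10,
                            class = "neuron", channel = "green"))
  asg <- assign_regions(nd, atlas)
  expect_identical(asg$region_id, 7L)
  # node over background and outside the grid stay unassigned and reported
  nd2 <- node_set(data.frame(id = 1:2, x_um = c(1, 1e6), y_um = c(1, 1),
                             z_um = c(1, 1), class = "neuron",
                             channel = "green"))
  asg2 <- assign_regions(nd2, atlas)
  expect_true(all(is.na(asg2$region_id)))
  expect_equal(attr(asg2, "report")$unassigned, 1:2)
  expect_equal(attr(asg2, "report")$out_of_bounds, 2L)
  # fixture nodes assign back to their generating regions, all of them
  fx <- table2_fixture(atlas)
  reasg <- assign_regions(node_set(as.data.frame(fx)), atlas)
  expect_identical(reasg$region_id, fx$region_id)
})

test_that("aggregation reproduces every printed cell of the count table", {
  atlas <- toy_atlas()
  tab <- aggregate_counts(table2_fixture(atlas), atlas)
  ref <- clearbrain:::table2_counts()
  inj <- ref$injection_site
  # every leaf, both classes, all three hemisphere columns
  expect_equal(tab$leaves$region, ref$region)
  expect_equal(tab$leaves$inj_neurons, ifelse(inj, ref$ipsi_neurons, 0))
  expect_equal(tab$leaves$inj_glia, ifelse(inj, ref$ipsi_glia, 0))
  expect_equal(tab$leaves$ipsi_neurons, ifelse(inj, 0, ref$ipsi_neurons))
  expect_equal(tab$leaves$ipsi_glia, ifelse(inj, 0, ref$ipsi_glia))
  expect_equal(tab$leaves$contra_neurons, ref$contra_neurons)
  expect_equal(tab$leaves$contra_glia, ref$contra_glia)
  # published rollups
  r <- tab$rollups
  expect_equal(r$ipsi_neurons, c(2385, 325, 863, 110))
  expect_equal(r$ipsi_glia, c(17, 5, 880, 1))
  expect_equal(r$contra_neurons, c(58, 22, 5, 0))
  expect_equal(r$inj_neurons, c(2319, 0, 0, 0))
  expect_equal(r$inj_glia, c(32, 0, 0, 0))
  expect_equal(unlist(tab$totals), c(inj_neurons = 2319, inj_glia = 32,
                                     ipsi_neurons = 3683, ipsi_glia = 903,
                                     contra_neurons = 85, contra_glia = 0))
  # injection-site leaf example
  expect_equal(tab$leaves$inj_neurons[tab$leaves$region ==
                                        "Lateral Entorhinal Cortex"], 1536)
})

test_that("derived fractions match the published percentages", {
  atlas <- toy_atlas()
  fr <- derived_fractions(aggregate_counts(table2_fixture(atlas), atlas))
  expect_equal(fr$hippocampal_glia_pct, 50.5)
  expect_equal(fr$extra_hippocampal_glia_pct, 0.8)
  expect_equal(fr$contralateral_input_pct, 2.3)
  expect_lte(fr$contralateral_input_pct, 3)
  expect_equal(fr$counts$hippocampal_glia, 880)
  # all-neuron table: glia fractions 0, undefined denominators reported NA
  nd <- node_set(data.frame(id = 1:4, x_um = 15, y_um = 15, z_um = 25,
                            class = "neuron", channel = "green"))
  asg <- assign_regions(nd, atlas)
  fr2 <- derived_fractions(aggregate_counts(asg, atlas))
  expect_equal(fr2$extra_hippocampal_glia_pct, 0)
  expect_true(is.na(fr2$hippocampal_glia_pct))
  expect_match(fr2$notes, "hippocampal", all = FALSE)
})

test_that("aggregation equals an independent tally on random node sets", {
  atlas <- toy_atlas()
  set.seed(10)
  d <- dim(atlas$labels)
  nd <- node_set(data.frame(
    id = 1:1000,
    x_um = stats::runif(1000, 0, d[3] * 10),
    y_um = stats::runif(1000, 0, d[2] * 10),
    z_um = stats::runif(1000, 0, d[1] * 10),
    class = sample(c("neuron", "glia"), 1000, replace = TRUE),
    channel = sample(c("green", "red", "both"), 1000, replace = TRUE)))
  asg <- assign_regions(nd, atlas)
  tab <- aggregate_counts(asg, atlas, allow_unassigned = TRUE)
  tl <- oracle_tally(asg, atlas)
  for (g in c("cortical", "subcortical", "hippocampal", "olfactory")) {
    r <- tab$rollups[tab$rollups$group == g, ]
    gv <- function(h, cl) if (g %in% dimnames(tl)[[1]] &&
                              h %in% dimnames(tl)[[2]])
      tl[g, h, cl] %||% 0 else 0
    expect_equal(r$ipsi_neurons, unname(gv("ipsilateral", "neuron")))
    expect_equal(r$ipsi_glia, unname(gv("ipsilateral", "glia")))
    expect_equal(r$contra_neurons, unname(gv("contralateral", "neuron")))
    expect_equal(r$inj_neurons, unname(gv("ipsilateral_inj", "neuron")))
  }
  # red-only nodes never enter the EGFP table
  expect_equal(sum(unlist(tab$totals)),
               sum(asg$channel != "red" & !is.na(asg$region_id)))
  # unassigned nodes are an error unless explicitly allowed
  expect_error(aggregate_counts(asg, atlas), "unassigned")
})

test_that("counts are conserved and permutation invariant", {
  atlas <- toy_atlas()
  fx <- table2_fixture(atlas)
  set.seed(2)
  shuf <- node_set(as.data.frame(fx)[sample(nrow(fx)), ])
  t1 <- aggregate_counts(fx, atlas)
  t2 <- aggregate_counts(shuf, atlas)
  expect_equal(t1$rollups, t2$rollups)
  expect_equal(t1$totals, t2$totals)
  count_cols <- c("inj_neurons", "inj_glia", "ipsi_neurons", "ipsi_glia",
                  "contra_neurons", "contra_glia")
  expect_equal(colSums(t1$leaves[, count_cols]),
               colSums(t1$rollups[, count_cols]))
  expect_equal(unname(unlist(t1$totals)),
               unname(colSums(t1$leaves[, count_cols])))
})

test_that("reports round-trip and mirror the printed layout", {
  atlas <- toy_atlas()
  tab <- aggregate_counts(table2_fixture(atlas), atlas)
  stats <- derived_fractions(tab)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "table2.tsv")
  md <- report_counts(tab, stats, path)
  back <- read_region_report(path)
  expect_equal(back$rollups, tab$rollups)
  expect_equal(unlist(back$totals), unlist(tab$totals))
  expect_equal(back$leaves$ipsi_neurons, tab$leaves$ipsi_neurons)
  # markdown rows: header (2) + non-empty leaves + 4 rollups + total
  count_cols <- c("inj_neurons", "inj_glia", "ipsi_neurons", "ipsi_glia",
                  "contra_neurons", "contra_glia")
  nonempty <- sum(rowSums(tab$leaves[, count_cols]) > 0)
  expect_equal(sum(grepl("^\\|", md)), 2 + nonempty + 4 + 1)
  # empty table: header-only file
  nd <- node_set()
  t0 <- aggregate_counts(nd, atlas)
  p0 <- file.path(dir, "empty.tsv")
  report_counts(t0, path = p0)
  parsed <- utils::read.table(p0, sep = "\t", header = TRUE)
  expect_true(all(rowSums(parsed[parsed$row_type == "leaf", count_cols]) == 0))
})
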
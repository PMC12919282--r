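test_that("BuD counting follows the distinct birder-day definition", {
  # three postings, same birder, same day -> one Birder User Day
  cl <- make_checklists(rep("b1", 3), rep("h1", 3), rep("2013-04-10", 3),
                        list("A", "B", "C"))
  buds <- aggregate_buds(cl, "h1", EPOCH, 3)
  expect_equal(buds$bud_count, c(1L, 0L, 0L))

  # two birders on two distinct days each -> four
  cl2 <- make_checklists(c("b1", "b1", "b2", "b2"), rep("h1", 4),
                         c("2013-05-01", "2013-05-02", "2013-05-03",
                           "2013-05-04"),
                         list("A", "A", "A", "A"))
  expect_equal(aggregate_buds(cl2, "h1", EPOCH, 3)$bud_count, c(0L, 4L, 0L))
})

test_that("aggregation flags bad input", {
  cl <- make_checklists("b1", "h1", "2013-04-10", list("A"))
  expect_warning(out <- aggregate_buds(cl, "nowhere", EPOCH, 2),
                 "no checklists")
  expect_equal(out$bud_count, c(0L, 0L))
  cl$date <- "not-a-date"
  expect_error(aggregate_buds(cl, "h1", EPOCH, 2), "malformed date")
})

test_that("monthly richness uses set semantics and the long list", {
  cl <- make_checklists(c("b1", "b2"), c("h1", "h1"),
                        c("2013-04-05", "2013-04-20"),
                        list(c("A", "B"), c("B", "C")))
  r <- monthly_richness(cl, "h1", EPOCH, 2)
  expect_equal(r$richness_all, c(3L, 0L))
  r2 <- monthly_richness(cl, "h1", EPOCH, 2, longlist = "B")
  expect_equal(r2$richness_water, c(1L, 0L))
  # permuting rows changes nothing
  perm <- cl[rev(seq_len(nrow(cl))), ]
  expect_equal(monthly_richness(perm, "h1", EPOCH, 2, longlist = "B"),
               r2)
  # matching is exact after trimming and case-folding
  cl$species <- c(" a", "B ", "b", "C")
  r3 <- monthly_richness(cl, "h1", EPOCH, 2, longlist = c("A", "b"))
  expect_equal(r3$richness_all[1], 3L)
  expect_equal(r3$richness_water[1], 2L)
})

test_that("descriptive statistics match the hand-computed case", {
  cl <- make_checklists(c("b1", "b1"), c("h1", "h1"),
                        c("2013-04-10", "2013-04-10"),
                        list(c("A", "B", "C"), c("D", "E", "F")))
  d <- descriptive_stats(cl)
  expect_false(d$empty)
  expect_equal(d$n_checklists, 2L)
  expect_equal(d$postings_per_birder, 2)
  expect_equal(d$species_per_list, 3)
  expect_equal(d$visit_days_per_birder, 1)
  expect_equal(d$hotspots_per_birder, 1)

  # duplicating the table (fresh birders and ids) doubles totals only
  cl2 <- cl
  cl2$birder_id <- paste0(cl2$birder_id, "x")
  cl2$checklist_id <- paste0(cl2$checklist_id, "x")
  d2 <- descriptive_stats(rbind(cl, cl2))
  expect_equal(d2$n_checklists, 2L * d$n_checklists)
  expect_equal(d2$n_visit_days, 2L * d$n_visit_days)
  expect_equal(d2$postings_per_birder, d$postings_per_birder)
  expect_equal(d2$species_per_list, d$species_per_list)
})

test_that("empty input returns the empty-summary sentinel", {
  d <- descriptive_stats(make_checklists(character(), character(),
                                         character(), list()))
  expect_true(d$empty)
  expect_true(is.na(d$postings_per_birder))
})

test_that("aggregation agrees with brute-force recounts on random fixtures", {
  set.seed(2718)
  for (rep in 1:5) {
    n <- 200
    cl <- data.frame(
      checklist_id = sprintf("c%03d", seq_len(n)),
      birder_id = sample(sprintf("b%02d", 1:12), n, replace = TRUE),
      hotspot_id = sample(c("h1", "h2"), n, replace = TRUE),
      date = EPOCH + sample.int(170, n, replace = TRUE) - 1L)
    cl <- cl[rep(seq_len(n), times = sample(1:4, n, replace = TRUE)), ]
    cl$species <- sample(LETTERS[1:8], nrow(cl), replace = TRUE)
    n_months <- 6L
    for (h in c("h1", "h2")) {
      buds <- aggregate_buds(cl, h, EPOCH, n_months)
      rich <- monthly_richness(cl, h, EPOCH, n_months, longlist = c("A", "B"))
      for (m in seq_len(n_months)) {
        sub <- cl[cl$hotspot_id == h &
                    date_month_index(cl$date, EPOCH) == m, ]
        expect_equal(buds$bud_count[m],
                     nrow(unique(sub[c("birder_id", "date")])))
        expect_equal(rich$richness_all[m],
                     length(unique(casefold(trimws(sub$species)))))
        expect_equal(rich$richness_water[m],
                     length(intersect(unique(casefold(trimws(sub$species))),
                                      c("a", "b"))))
      }
      # window total equals the distinct (birder, date, hotspot) triples
      inwin <- cl[cl$hotspot_id == h &
                    date_month_index(cl$date, EPOCH) <= n_months, ]
      expect_equal(sum(buds$bud_count),
                   nrow(unique(inwin[c("birder_id", "date")])))
      # de-duplication leaves aggregation unchanged
      expect_equal(aggregate_buds(unique(cl), h, EPOCH, n_months), buds)
      expect_true(all(rich$richness_water <= rich$richness_all))
    }
  }
})

test_that("build_panel stacks complete windows with zero months explicit", {
  cfg <- small_cfg(seed = 21, n_months = 12, n_birders = 25)
  cl <- sim_checklists(cfg)
  pool <- species_pool(cfg)
  expect_warning(
    pan <- build_panel(cl, cfg$epoch, cfg$n_months,
                       hotspots = c("h01", "h99"),
                       longlist = pool$species[pool$water_related]),
    "no checklists")
  expect_equal(nrow(pan), 24L)
  expect_equal(unique(table(pan$hotspot_id)), 12L)
  expect_true(all(pan$richness_water <= pan$richness_all))
  expect_true(all(pan$richness_all <= cfg$n_species))
  expect_true(all(pan$bud_count[pan$hotspot_id == "h99"] == 0L))
  truth <- attr(cl, "truth")
  expect_identical(pan$bud_count[pan$hotspot_id == "h01"], truth$bud)
})
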
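published_rows <- data.frame(
  strategy = c("LAP_APPY", "INPATIENT_NOM", "OUTPATIENT_NOM"),
  cost = c(236200, 241000, 233700),
  qaly = c(25.0043, 24.9279, 24.9270),
  ly = c(26.5976, 26.5272, 26.5267))

test_that("incremental analysis reproduces the published example", {
  tab <- incremental_analysis(published_rows, wtp = 50000)
  expect_true(tab$dominated[tab$strategy == "INPATIENT_NOM"])
  la <- tab[tab$strategy == "LAP_APPY", ]
  expect_false(la$dominated)
  expect_equal(la$comparator, "OUTPATIENT_NOM")
  expect_equal(la$icer, 2500 / 0.0773, tolerance = 1e-12)
  expect_equal(la$icer, 32341.5265, tolerance = 1e-8)
  expect_equal(la$icer_rounded, 32300)
  expect_equal(preferred_strategy(tab), "LAP_APPY")
})

test_that("exact duplicates are resolved against the later row", {
  dup <- data.frame(strategy = c("A", "B"), cost = c(100, 100),
                    qaly = c(1, 1), ly = c(1, 1))
  tab <- incremental_analysis(dup, wtp = 50000)
  expect_equal(tab$strategy[tab$dominated], "B")
  # zero QALY gain at extra cost is dominated, never divided
  tie <- data.frame(strategy = c("A", "B"), cost = c(100, 200),
                    qaly = c(1, 1), ly = c(1, 1))
  tab2 <- incremental_analysis(tie, wtp = 50000)
  expect_true(tab2$dominated[tab2$strategy == "B"])
  expect_true(all(is.na(tab2$icer[tab2$dominated])))
})

test_that("extended dominance removes mid-frontier kinks", {
  # middle strategy's segment ICER exceeds the next segment's
  df <- data.frame(strategy = c("A", "B", "C"),
                   cost = c(0, 1000, 1500),
                   qaly = c(0, 0.01, 0.05), ly = c(1, 1, 1))
  tab <- incremental_analysis(df, wtp = 1e9)
  expect_true(tab$ext_dominated[tab$strategy == "B"])
  expect_equal(tab$icer[tab$strategy == "C"], 1500 / 0.05)
  # on a straight line with increasing ICERs nothing is excluded
  df2 <- data.frame(strategy = c("A", "B", "C"),
                    cost = c(0, 1000, 3000),
                    qaly = c(0, 0.05, 0.10), ly = c(1, 1, 1))
  tab2 <- incremental_analysis(df2, wtp = 1e9)
  expect_false(any(tab2$ext_dominated))
})

test_that("net monetary benefit behaves at its edges", {
  r <- list(strategy = "X", cost = 1000, qaly = 2, ly = 2)
  expect_equal(net_monetary_benefit(r, 0), -1000)
  nmb <- net_monetary_benefit(published_rows, 50000)
  expect_equal(published_rows$strategy[which.max(nmb)], "LAP_APPY")
  eq <- data.frame(strategy = c("A", "B"), cost = c(50, 40), qaly = c(1, 1))
  expect_equal(eq$strategy[which.max(net_monetary_benefit(eq, 7e4))], "B")
})

test_that("NMB argmax coincides with the frontier-preferred strategy", {
  set.seed(77)
  for (i in 1:1000) {
    k <- sample(2:4, 1)
    df <- data.frame(strategy = paste0("S", 1:k),
                     cost = runif(k, 0, 3e5),
                     qaly = runif(k, 10, 30), ly = 30)
    wtp <- runif(1, 0, 2e5)
    expect_equal(preferred_strategy(incremental_analysis(df, wtp)),
                 appendcea:::.nmb_preferred(df, wtp))
  }
})

test_that("adding a dominated strategy leaves frontier ICERs unchanged", {
  tab <- incremental_analysis(published_rows, wtp = 50000)
  extra <- rbind(published_rows,
                 data.frame(strategy = "WORSE", cost = 3e5, qaly = 24,
                            ly = 26))
  tab2 <- incremental_analysis(extra, wtp = 50000)
  expect_true(tab2$dominated[tab2$strategy == "WORSE"])
  la1 <- tab$icer[tab$strategy == "LAP_APPY"]
  la2 <- tab2$icer[tab2$strategy == "LAP_APPY"]
  expect_equal(la1, la2)
})
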
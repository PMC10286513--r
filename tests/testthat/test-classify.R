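sampleSheet <- data.frame(
    stage = rep(c("bud", "flower_1DPA"), each = 4),
    time = rep(rep(c("morning", "evening"), each = 2), 2),
    replicate = rep(1:2, 4),
    row.names = paste0("s", 1:8))

test_that("expressed sets use an inclusive mean threshold per condition", {
    norm <- rbind(at30  = c(rep(0, 4), 30, 30, 0, 0),
                  just_below = c(rep(0, 4), 29.99, 29.99, 0, 0),
                  evening_only = c(rep(0, 6), 500, 500),
                  bud_gene = c(40, 40, 0, 0, 0, 0, 0, 0))
    colnames(norm) <- paste0("s", 1:8)
    e1 <- expressedSet(norm, sampleSheet, "flower_1DPA")
    expect_setequal(e1, c("at30", "evening_only"))  # either time point counts
    expect_setequal(expressedSet(norm, sampleSheet, "flower_1DPA",
                                 time = "morning"), "at30")
    expect_setequal(expressedSet(norm, sampleSheet, "bud"), "bud_gene")
    expect_equal(length(expressedSet(norm * 0, sampleSheet, "bud")), 0)
    expect_error(expressedSet(norm, sampleSheet, "open"), "unknown stage")
})

test_that("venn partition reproduces the published stage overlap", {
    # generated sets with the study's printed sizes: 15,174 genes expressed
    # at 1DPA (1072 specific), 15,436 in buds (1334 specific)
    shared <- sprintf("sh%05d", seq_len(14102))
    a <- c(sprintf("fa%04d", seq_len(1072)), shared)
    b <- c(sprintf("fb%04d", seq_len(1334)), shared)
    v <- vennPartition(a, b)
    expect_equal(unname(v$sizes["a"]), 15174)
    expect_equal(unname(v$sizes["b"]), 15436)
    expect_equal(unname(v$sizes["shared"]), 14102)
    expect_equal(unname(v$sizes["union"]), 16508)
    # both reconstructions of the union agree
    expect_equal(unname(v$sizes["a"] + v$sizes["only_b"]),
                 unname(v$sizes["b"] + v$sizes["only_a"]))

    same <- vennPartition(letters, letters)
    expect_equal(unname(same$sizes[c("only_a", "only_b")]), c(0, 0))
    dis <- vennPartition(c("x", "y"), c("p", "q"))
    expect_equal(unname(dis$sizes["shared"]), 0)
    expect_equal(unname(dis$sizes["union"]), 4)
})

test_that("time partition splits DEG sets and preserves the union", {
    dm <- makeDE(c("A", "B", "C", "D"), c("up", "up", "ns", "down"))
    de <- makeDE(c("A", "B", "C", "D"), c("ns", "down", "up", "down"))
    p <- partitionByTime(dm, de)
    expect_setequal(p$morning_only, "A")
    expect_setequal(p$evening_only, "C")
    expect_setequal(p$both, c("B", "D"))
    expect_equal(length(p$morning_only) + length(p$evening_only) +
                     length(p$both), 4)
    expect_setequal(p$up$both, character(0))
    expect_setequal(p$down$both, "D")

    noneE <- makeDE(c("A", "B", "C", "D"), rep("ns", 4))
    p2 <- partitionByTime(dm, noneE)
    expect_equal(length(p2$both), 0)
    expect_setequal(p2$morning_only, c("A", "B", "D"))
    expect_error(partitionByTime(dm, makeDE("Z", "up")), "universes")
})

test_that("reversal groups are direction-crossed and disjoint", {
    dm <- makeDE(c("A", "B", "C"), c("up", "up", "down"))
    de <- makeDE(c("A", "B", "C"), c("up", "down", "up"))
    r <- reversalGroups(dm, de)
    expect_setequal(r$up_m_down_e, "B")
    expect_setequal(r$down_m_up_e, "C")
    expect_equal(length(intersect(r$up_m_down_e, r$down_m_up_e)), 0)
})

test_that("planted morning-only developmental effects are recovered", {
    cfg <- effectConfig(frac_stage_de = 0.25, frac_time_de_bud = 0,
                        frac_time_de_flower = 0,
                        stage_timing_split = c(morning_only = 1,
                                               evening_only = 0, both = 0),
                        lfc_distribution = c(mean = 2, sd = 0),
                        plant_candidates = FALSE, seed = 31)
    sim <- simulateCounts(experimentDesign(n_genes = 1000), cfg)
    dm <- runDE(sim$ce, "stage", "flower_1DPA", "bud",
                at = c(time = "morning"))
    de <- runDE(sim$ce, "stage", "flower_1DPA", "bud",
                at = c(time = "evening"))
    p <- partitionByTime(dm, de)
    strong <- sim$truth$base_mean >= 100
    truthSet <- sim$truth$gene[strong & sim$truth$lfc_stage_morning != 0]
    recovered <- intersect(p$morning_only, sim$truth$gene[strong])
    jac <- length(intersect(recovered, truthSet)) /
        length(union(recovered, truthSet))
    expect_gte(jac, 0.8)
})

test_that("percentage report reproduces the published arithmetic", {
    rep <- summaryPercentages(petuniaSetSizes())
    pct <- setPercentages(rep)
    expect_equal(unname(pct["pct_me_1DPA"]), 42)        # 6386 / 15,174
    expect_equal(unname(pct["pct_me_bud"]), 17.2)       # 2656 / 15,436
    expect_equal(unname(pct["pct_shared_of_bud"]), 65)  # 1729 / 2656
    expect_equal(unname(pct["pct_shared_of_1DPA"]), 27)
    expect_equal(unname(pct["pct_both_stage_expr"]), 92)
    expect_equal(unname(pct["pct_me_union"]), 44)
    expect_equal(unname(pct["pct_total_dev_DEG"]), 70)
    cnt <- setCounts(rep)
    expect_equal(unname(cnt["expressed_union"]), 16508)
    expect_equal(unname(cnt["stage_specific_1DPA"]), 1072)
    expect_equal(unname(cnt["stage_specific_bud"]), 1334)
    # the 1DPA/bud diurnal-response ratios straddle the quoted 2.5-fold
    expect_equal(unname(rep@ratios["me_response_count_ratio"]),
                 6386 / 2656, tolerance = 1e-12)
    expect_equal(unname(rep@ratios["me_response_pct_ratio"]),
                 (6386 / 15174) / (2656 / 15436), tolerance = 1e-12)
})

test_that("report percentages are self-consistent and bounded", {
    sz <- c(expressed_1DPA = 100, expressed_bud = 100,
            expressed_shared = 100, dev_deg = 100, me_deg_1DPA = 100,
            me_deg_bud = 100, me_deg_shared = 100,
            me_deg_1DPA_expressed_both = 100)
    rep <- summaryPercentages(sz)
    expect_true(all(setPercentages(rep) == 100))

    # every percentage is recomputable from the emitted counts alone
    r2 <- summaryPercentages(petuniaSetSizes())
    cnt <- setCounts(r2)
    expect_equal(unname(setPercentages(r2)["pct_me_1DPA"]),
                 roundHalfUp(100 * cnt[["me_deg_1DPA"]] /
                                 cnt[["expressed_1DPA"]]))
    expect_equal(unname(setPercentages(r2)["pct_me_union"]),
                 roundHalfUp(100 * cnt[["me_deg_union"]] /
                                 cnt[["expressed_union"]]))

    bad <- petuniaSetSizes(); bad["me_deg_bud"] <- 0
    expect_error(summaryPercentages(bad), "zero denominator")
    expect_error(summaryPercentages(petuniaSetSizes()[-1]), "missing")
})

test_that("half-up rounding differs from banker's rounding where it must", {
    expect_equal(roundHalfUp(0.5), 1)
    expect_equal(roundHalfUp(1.5), 2)
    expect_equal(roundHalfUp(2.5), 3)     # round() would give 2
    expect_equal(roundHalfUp(-0.5), -1)
    expect_equal(roundHalfUp(17.25, 1), 17.3)
})
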
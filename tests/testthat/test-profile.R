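params <- scoringParams()

test_that("local alignment scores match the brute-force DP oracle", {
    set.seed(101)
    for (i in 1:25) {
        a <- randomProtein(sample(5:40, 1))
        b <- randomProtein(sample(5:40, 1))
        expect_equal(swAlign(a, b, params)$score,
                     swOracle(a, b, params$mat, params$gap_open,
                              params$gap_extend),
                     info = paste(a, b))
    }
})

test_that("alignment degenerate cases behave as local alignment must", {
    s <- "MKWVTFISLLLLFSSAYS"
    diag <- sum(diag(params$mat[strsplit(s, "")[[1]], strsplit(s, "")[[1]]]))
    expect_equal(swAlign(s, s, params)$score, diag)
    # no positively scoring residue pair -> empty alignment, score 0
    expect_equal(swAlign("WWWW", "PPPP", params)$score, 0)
    # ambiguity codes map to X; anything else is rejected
    expect_no_error(swAlign("MKBZUOW", "MKXW", params))
    expect_error(swAlign("MK1W", "MKW", params), "illegal residue")
    expect_error(swAlign("", "MKW", params), "non-empty")
})

test_that("bit scores follow the Karlin-Altschul transform", {
    expect_equal(bitScore(100, params),
                 (0.267 * 100 - log(0.041)) / log(2), tolerance = 1e-12)
    expect_equal(bitScore(100, params), 43.13, tolerance = 0.005)
    expect_equal(bitScore(0, params), -log(0.041) / log(2))
    # strictly increasing in S
    expect_true(all(diff(bitScore(0:50, params)) > 0))
    expect_error(scoringParams(lambda = 0), "positive")
    expect_error(scoringParams(K = -1), "positive")
})

test_that("E-values scale with the search space", {
    e <- eValue(43.13, 300, 1e5)
    expect_equal(e, 3e7 * 2^(-43.13), tolerance = 1e-12)
    expect_lt(e, 1e-5)
    expect_equal(eValue(43.13, 300, 1e6), 10 * e, tolerance = 1e-12)
    # 2^-S' = 1/(mn) -> E = 1
    expect_equal(eValue(log2(300 * 1e5), 300, 1e5), 1, tolerance = 1e-12)
    expect_error(eValue(10, 0, 100), "positive")
})

test_that("best hit maximizes bits with a deterministic tie-break", {
    q <- randomProtein(60)
    prot <- Biostrings::AAStringSet(c(p_self = q,
                                      p_decoy = randomProtein(60)))
    h <- bestHit(q, prot, params)
    expect_equal(h$protein, "p_self")
    expect_equal(h$bits, bitScore(swAlign(q, q, params)$score, params))

    twins <- Biostrings::AAStringSet(c(zz = q, aa = q))
    expect_equal(bestHit(q, twins, params)$protein, "aa")
    expect_error(bestHit(q, Biostrings::AAStringSet(), params), "empty")
})

test_that("conservation scores are 100 for verbatim queries and zeroed by rule", {
    sim <- simulateProteomes(cladeSimConfig(
        clades = c(A = 2L, B = 2L), divergence = c(A = 0, B = 0.25),
        homolog_presence = c(A = 1, B = 1), decoys_per_organism = 2L,
        seed = 7))
    prof <- conservationProfile(sim$query, sim$collection, params)
    sc <- conservationScores(prof)
    expect_equal(unname(sc["A_org01"]), 100)     # query present verbatim
    expect_true(all(sc <= 100))                  # Pab <= Paa
    expect_true(all(sc == 0 | sc >= 10))         # zeroing rule invariant

    # E-value rule: an absurdly strict cutoff zeroes even the self hit
    strict <- scoringParams(evalue_max = 1e-300)
    expect_true(all(conservationScores(
        conservationProfile(sim$query, sim$collection, strict)) == 0))

    # percent rule: raising the floor above a diverged homolog's ratio
    # zeroes it even though its E-value passes
    loose <- conservationProfile(sim$query, sim$collection, params)
    bScore <- conservationScores(loose)["B_org01"]
    expect_gt(bScore, 10)
    highFloor <- scoringParams(cons_min_percent = bScore + 5)
    expect_equal(unname(conservationScores(
        conservationProfile(sim$query, sim$collection,
                            highFloor))["B_org01"]), 0)
})

test_that("mean conservation decreases with planted divergence", {
    cfg <- cladeSimConfig(clades = c(lo = 4L, mid = 4L, hi = 4L),
                          divergence = c(lo = 0.05, mid = 0.3, hi = 0.6),
                          homolog_presence = c(lo = 1, mid = 1, hi = 1),
                          decoys_per_organism = 1L, seed = 13)
    sim <- simulateProteomes(cfg)
    prof <- conservationProfile(sim$query, sim$collection, params)
    h <- prof@hits
    m <- vapply(c("lo", "mid", "hi"), function(cl)
        mean(h$conservation_score[h$clade == cl]), numeric(1))
    expect_true(all(diff(m) <= 0))
})

test_that("clade restriction requires a single clade above threshold", {
    sim <- simulateProteomes(cladeSimConfig(seed = 21))
    prof <- conservationProfile(sim$query, sim$collection, params)
    r <- cladeRestriction(prof)
    expect_equal(r$restricted_to, "Viridiplantae")
    expect_equal(unname(r$clade_counts[c("Metazoa", "Fungi")]), c(0, 0))

    fake <- function(scores, clades) {
        hits <- S4Vectors::DataFrame(
            organism = paste0("o", seq_along(scores)), clade = clades,
            best_protein = "p", raw_score = 1, bits = 1, evalue = 1e-9,
            conservation_score = scores)
        methods::new("ConservationProfile", hits = hits, query = "q",
                     selfBits = 1, params = list(cons_min_percent = 10))
    }
    two <- cladeRestriction(fake(c(50, 15, 0), c("X", "Y", "Y")))
    expect_true(is.na(two$restricted_to))
    none <- cladeRestriction(fake(c(0, 0), c("X", "Y")))
    expect_true(is.na(none$restricted_to))
    expect_equal(none$n_above, 0)
})
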
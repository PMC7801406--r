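test_that("a clean three-community dataset loads with validated dimensions", {
    dir <- withr::local_tempdir()
    paths <- writeDatasetCSVs(dir, nSites = 12)
    ds <- suppressMessages(loadDataset(paths[c("birds", "invertebrates", "plants")],
                                       paths[["metadata"]]))
    expect_named(ds$communities, c("birds", "invertebrates", "plants"))
    expect_equal(nrow(ds$metadata), 12)
    expect_equal(dim(ds$hydro), c(12L, 4L))
    for (cm in ds$communities) {
        expect_s4_class(cm, "CommunityMatrix")
        expect_equal(dim(cm), c(12L, 5L))
        expect_true(all(abundances(cm) >= 0))
    }
})

test_that("loader rejects duplicate sites, unknown classes, negatives and blanks by name", {
    dir <- withr::local_tempdir()
    paths <- writeDatasetCSVs(dir, nSites = 8)

    bad <- utils::read.csv(paths[["birds"]], check.names = FALSE)
    bad$site_id[2] <- bad$site_id[1]
    utils::write.csv(bad, file.path(dir, "dup.csv"), row.names = FALSE)
    expect_error(
        suppressMessages(loadDataset(c(birds = file.path(dir, "dup.csv")),
                                     paths[["metadata"]])),
        bad$site_id[1])

    neg <- utils::read.csv(paths[["birds"]], check.names = FALSE)
    neg[3, 2] <- -1
    utils::write.csv(neg, file.path(dir, "neg.csv"), row.names = FALSE)
    expect_error(
        suppressMessages(loadDataset(c(birds = file.path(dir, "neg.csv")),
                                     paths[["metadata"]])),
        "negative")

    hole <- utils::read.csv(paths[["birds"]], check.names = FALSE)
    hole[4, 3] <- NA
    utils::write.csv(hole, file.path(dir, "hole.csv"), row.names = FALSE)
    expect_error(
        suppressMessages(loadDataset(c(birds = file.path(dir, "hole.csv")),
                                     paths[["metadata"]])),
        "missing")

    meta <- utils::read.csv(paths[["metadata"]])
    meta$permanence_class[1] <- "ephemeral"
    utils::write.csv(meta, file.path(dir, "badmeta.csv"), row.names = FALSE)
    err <- tryCatch(
        suppressMessages(loadDataset(paths["birds"], file.path(dir, "badmeta.csv"))),
        error = conditionMessage)
    expect_match(err, "ephemeral")
    expect_match(err, "temporary, seasonal, semi-permanent, permanent")
})

test_that("exclude lists drop named columns (non-vascular cover classes)", {
    dir <- withr::local_tempdir()
    paths <- writeDatasetCSVs(dir, nSites = 8)
    df <- utils::read.csv(paths[["plants"]], check.names = FALSE)
    df$litter <- 1; df$`bare ground` <- 2
    utils::write.csv(df, paths[["plants"]], row.names = FALSE)
    ds <- suppressMessages(loadDataset(paths["plants"], paths[["metadata"]],
        exclude = list(plants = c("litter", "bare ground"))))
    expect_false(any(c("litter", "bare ground") %in%
                         taxonIds(ds$communities$plants)))
    expect_equal(ncol(ds$communities$plants), 5L)
})

test_that("alignment restricts to the lexicographic common site set and is idempotent", {
    dir <- withr::local_tempdir()
    paths <- writeDatasetCSVs(dir, nSites = 10)
    ds <- suppressMessages(loadDataset(paths[c("birds", "plants")],
                                       paths[["metadata"]]))
    ## shuffle one matrix's rows and drop a site from the other
    v <- abundances(ds$communities$birds)
    ds$communities$birds <- communityMatrix(v[rev(rownames(v)), ], "birds")
    vp <- abundances(ds$communities$plants)
    ds$communities$plants <- communityMatrix(vp[-4, ], "plants")
    aligned <- suppressMessages(alignSites(ds))
    ids <- siteIds(aligned$communities$birds)
    expect_identical(ids, sort(ids))
    expect_length(ids, 9)
    expect_identical(ids, siteIds(aligned$communities$plants))
    expect_identical(ids, siteIds(aligned$hydro))
    expect_identical(ids, aligned$metadata$site_id)
    ## second alignment is a no-op
    again <- suppressMessages(alignSites(aligned))
    expect_identical(abundances(again$communities$birds),
                     abundances(aligned$communities$birds))
    expect_identical(again$metadata, aligned$metadata)
})

test_that("alignment refuses a site intersection below three", {
    dir <- withr::local_tempdir()
    paths <- writeDatasetCSVs(dir, nSites = 6)
    ds <- suppressMessages(loadDataset(paths[c("birds", "plants")],
                                       paths[["metadata"]]))
    v <- abundances(ds$communities$plants)
    rownames(v) <- paste0("X", rownames(v))  # disjoint site set
    ds$communities$plants <- communityMatrix(v, "plants")
    expect_error(suppressMessages(alignSites(ds)), "at least 3")
})

test_that("hydroperiod groups partition the permanence classes", {
    meta <- designMetadata()  # 30/35/17/14 by default
    short <- suppressMessages(assignGroup(meta, "short"))
    long <- suppressMessages(assignGroup(meta, "long"))
    all <- suppressMessages(assignGroup(meta, "all"))
    expect_length(short, 65)
    expect_length(long, 31)
    expect_length(all, 96)
    expect_identical(sort(c(short, long)), all)
    ## partition property holds for arbitrary class mixes
    set.seed(11)
    for (i in 1:5) {
        counts <- stats::setNames(sample(1:20, 4),
            c("temporary", "seasonal", "semi-permanent", "permanent"))
        m <- designMetadata(counts)
        expect_length(
            suppressMessages(c(assignGroup(m, "short"), assignGroup(m, "long"))),
            length(suppressMessages(assignGroup(m, "all"))))
    }
    expect_error(suppressMessages(
        assignGroup(meta[meta$permanence_class == "temporary", ], "long")),
        "no sites")
})
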
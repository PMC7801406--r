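# Shared fixture builders; everything is generated in code at test time.

randomConfig <- function(n, p, seed = NULL, prefix = "W") {
    if (!is.null(seed)) set.seed(seed)
    m <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(sprintf("%s%03d", prefix, seq_len(n)),
                                sprintf("c%02d", seq_len(p))))
    m
}

randomAbundance <- function(n, p, seed = NULL, lambda = 6) {
    if (!is.null(seed)) set.seed(seed)
    matrix(stats::rpois(n * p, lambda), n, p,
           dimnames = list(sprintf("W%03d", seq_len(n)),
                           sprintf("sp%02d", seq_len(p))))
}

# Site metadata with the given sites per permanence class, indicator
# values drawn as smooth functions of the class rank.
designMetadata <- function(counts = c(temporary = 30, seasonal = 35,
                                      `semi-permanent` = 17, permanent = 14)) {
    classes <- rep(names(counts), counts)
    n <- length(classes)
    rank <- (match(classes, c("temporary", "seasonal", "semi-permanent",
                              "permanent")) - 0.5) / 4
    data.frame(site_id = sprintf("W%03d", seq_len(n)),
               permanence_class = classes,
               days_ponded = round(365 * rank),
               max_depth_cm = round(120 * rank, 1),
               amplitude_ratio = round(1 - 0.8 * rank, 3),
               evap_index = round(1 - rank, 3))
}

writeDatasetCSVs <- function(dir, nSites = 12, seed = 99) {
    set.seed(seed)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    classes <- rep(c("temporary", "seasonal", "semi-permanent", "permanent"),
                   length.out = nSites)
    meta <- designMetadata(table(factor(classes,
        c("temporary", "seasonal", "semi-permanent", "permanent"))))
    meta <- meta[seq_len(nSites), ]
    utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
    paths <- c(metadata = file.path(dir, "metadata.csv"))
    for (lab in c("birds", "invertebrates", "plants")) {
        v <- randomAbundance(nSites, 5)
        rownames(v) <- meta$site_id
        df <- data.frame(site_id = rownames(v), v, check.names = FALSE)
        f <- file.path(dir, paste0(lab, ".csv"))
        utils::write.csv(df, f, row.names = FALSE)
        paths[lab] <- f
    }
    paths
}

# Independent brute-force oracle for 2-column configurations: grid search
# over the rotation angle (with reflection) maximizing the inner product
# of the centered, unit-sum-of-squares configurations. Never touches the
# SVD path.
angleGridR <- function(x, y, step = 1e-5) {
    prep <- function(m) {
        m <- sweep(m, 2, colMeans(m))
        m / sqrt(sum(m^2))
    }
    C <- crossprod(prep(x), prep(y))
    theta <- seq(0, 2 * pi, by = step)
    rot <- (C[1, 1] + C[2, 2]) * cos(theta) + (C[1, 2] - C[2, 1]) * sin(theta)
    ref <- (C[1, 1] - C[2, 2]) * cos(theta) + (C[1, 2] + C[2, 1]) * sin(theta)
    max(rot, ref)
}
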
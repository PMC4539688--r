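#' Pipeline run configuration
#'
#' Collects and validates every tunable of an end-to-end run. Defaults
#' follow the settings used for the real-data analyses: MAPQ 10, 600 bp
#' fragment-size cap, 1 kbp inward / 25 kbp outward gap minima, direct
#' filtering at five-fold over the non-specific ligation rate, loess
#' normalization, 5 % FDR.
#'
#' @param enzyme Enzyme string `"SEQ:offset"` (default HindIII).
#' @param bin_sizes One or more bin widths in bp; with several, the finest
#'   analyses are consolidated under the coarsest.
#' @param min_mapq,max_frag,min_inward,min_outward QC thresholds, see
#'   [classify_and_filter()].
#' @param filter_strategy `"direct"`, `"trend"`, `"peak"` or `"none"`.
#' @param filter_fold Fold for the direct filter.
#' @param peak_radius Radius for the peak filter.
#' @param normalization `"loess"`, `"scale"`, `"cnv"` or `"none"`.
#' @param loess_span Span for loess normalization.
#' @param fdr FDR threshold for reporting.
#' @param cluster_gap Gap for clustering significant bin pairs (bp).
#' @param exclude_chroms Chromosomes dropped before filtering (e.g. "chrY").
#' @param seed RNG seed recorded with the run.
#' @return A validated list of class `"RunConfig"`.
#' @export
pipeline_config <- function(enzyme = "AAGCTT:1", bin_sizes = 1e6,
                            min_mapq = 10, max_frag = 600,
                            min_inward = 1000, min_outward = 25000,
                            filter_strategy = c("direct", "trend", "peak", "none"),
                            filter_fold = 5, peak_radius = 2,
                            normalization = c("loess", "scale", "cnv", "none"),
                            loess_span = 0.3, fdr = 0.05, cluster_gap = 0,
                            exclude_chroms = character(0), seed = 1) {
    filter_strategy <- match.arg(filter_strategy)
    normalization <- match.arg(normalization)
    parse_enzyme(enzyme)   # validates
    stopifnot(length(bin_sizes) >= 1, all(bin_sizes >= 1),
              min_mapq >= 0, max_frag >= 0, min_inward >= 0, min_outward >= 0,
              filter_fold >= 1, fdr > 0, fdr <= 1, cluster_gap >= 0)
    structure(
        list(enzyme = enzyme, bin_sizes = sort(as.numeric(bin_sizes)),
             min_mapq = min_mapq, max_frag = max_frag,
             min_inward = min_inward, min_outward = min_outward,
             filter_strategy = filter_strategy, filter_fold = filter_fold,
             peak_radius = peak_radius, normalization = normalization,
             loess_span = loess_span, fdr = fdr, cluster_gap = cluster_gap,
             exclude_chroms = exclude_chroms, seed = seed),
        class = "RunConfig"
    )
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `"RunConfig"`.
#' @export
read_pipeline_config <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(pipeline_config))
    unknown <- setdiff(names(vals), known)
    if (length(unknown)) {
        stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
    }
    do.call(pipeline_config, vals)
}

#' Run the full differential-interaction pipeline
#'
#' Orchestrates prepare (QC) -> count -> filter -> normalize -> test ->
#' consolidate over one or more bin sizes, with a log of counts in and out
#' of every stage. No new computation happens here; every stage is one of
#' the exported functions.
#'
#' @param inputs Either a named list of `"hic_pairs"` objects (one per
#'   library; already loaded) or a named character vector of name-sorted
#'   SAM/BAM paths.
#' @param group Condition factor, one level per library.
#' @param genome Genome (FASTA path / named character vector) used to build
#'   the fragment map; required when `inputs` are file paths or QC is to be
#'   (re)applied.
#' @param config A `"RunConfig"` (default [pipeline_config()]).
#' @param outdir Optional directory: every intermediate is persisted as TSV
#'   (with the config echoed as `config.yaml`).
#' @return A result bundle: list with `config`, `qc` (per-library
#'   PairFilterStats), `analyses` (per bin size: counts, filter decision,
#'   offsets, results), `consolidated` (with >1 bin size), `clusters`, and
#'   `log` (character vector).
#' @export
run_pipeline <- function(inputs, group, genome = NULL,
                         config = pipeline_config(), outdir = NULL) {
    stopifnot(inherits(config, "RunConfig"))
    set.seed(config$seed)
    logline <- character(0)
    say <- function(...) {
        msg <- sprintf(...)
        logline <<- c(logline, msg)
        message(msg)
    }
    enz <- parse_enzyme(config$enzyme)
    fragmap <- if (!is.null(genome)) fragment_map(genome, enz) else NULL

    # ---- prepare ----------------------------------------------------------
    if (is.character(inputs)) {
        if (is.null(fragmap)) stop("prepare stage: genome required for file input")
        if (is.null(names(inputs))) names(inputs) <- paste0("lib", seq_along(inputs))
        inputs <- lapply(inputs, load_hic_pairs, fragmap = fragmap)
    }
    if (length(inputs) != length(group)) {
        stop("prepare stage: one group label per library required")
    }
    qc <- NULL
    if (!is.null(fragmap)) {
        filtered <- lapply(names(inputs), function(nm) {
            res <- classify_and_filter(inputs[[nm]],
                                       min_mapq = config$min_mapq,
                                       max_frag = config$max_frag,
                                       min_inward = config$min_inward,
                                       min_outward = config$min_outward)
            say("prepare: %s %d pairs in, %d retained", nm,
                res$stats[["input"]], res$stats[["retained"]])
            res
        })
        names(filtered) <- names(inputs)
        qc <- lapply(filtered, `[[`, "stats")
        inputs <- lapply(filtered, `[[`, "pairs")
    }

    # ---- per-bin-size analyses -------------------------------------------
    analyses <- lapply(config$bin_sizes, function(width) {
        if (is.null(fragmap)) stop("count stage: genome required to build bins")
        binmap <- build_bins(fragmap, width)
        cm <- count_pairs(inputs, binmap)
        say("count: width %g -> %d bin pairs over %d bins (%s pairs counted)",
            width, nrow(cm$counts), n_bins(binmap),
            paste(cm$totals, collapse = "/"))
        if (length(config$exclude_chroms)) {
            cm <- exclude_chromosomes(cm, config$exclude_chroms)
        }
        decision <- switch(config$filter_strategy,
            direct = direct_filter(cm, fold = config$filter_fold),
            trend = trend_filter(cm, fold = config$filter_fold),
            peak = peak_filter(cm, radius = config$peak_radius),
            none = structure(list(keep = rep(TRUE, nrow(cm$counts)),
                                  threshold = -Inf, strategy = "none"),
                             class = "FilterDecision"))
        kept <- apply_filter(cm, decision)
        say("filter (%s): %d of %d bin pairs kept", config$filter_strategy,
            nrow(kept$counts), nrow(cm$counts))
        offsets <- switch(config$normalization,
            loess = loess_offsets(kept, span = config$loess_span),
            scale = scaling_offsets(kept),
            cnv = cnv_offsets(kept),
            none = libsize_offsets(kept))
        say("normalize: %s offsets computed", config$normalization)
        design <- hic_design(group)
        results <- test_interactions(kept, design, offsets)
        say("test: %d bin pairs tested, %d at FDR <= %g",
            nrow(results), sum(results$FDR <= config$fdr, na.rm = TRUE),
            config$fdr)
        list(width = width, binmap = binmap, counts = cm, filter = decision,
             filtered_counts = kept, offsets = offsets, results = results)
    })
    names(analyses) <- paste0("width_", format(config$bin_sizes,
                                               scientific = FALSE))

    # ---- consolidate ------------------------------------------------------
    consolidated <- NULL
    if (length(analyses) > 1) {
        finest <- analyses[[1]]
        coarsest <- analyses[[length(analyses)]]
        consolidated <- consolidate_resolutions(
            finest$results, coarsest$binmap, coarsest$results)
        say("consolidate: %d parent bin pairs, %d at FDR <= %g",
            nrow(consolidated),
            sum(consolidated$FDR <= config$fdr, na.rm = TRUE), config$fdr)
    }
    last <- analyses[[length(analyses)]]
    clusters <- cluster_results(last$results, max_gap = config$cluster_gap,
                                significant_only = TRUE,
                                fdr_threshold = config$fdr)
    say("cluster: %d cluster(s) among significant bin pairs",
        nrow(clusters$clusters))

    bundle <- list(config = config, qc = qc, analyses = analyses,
                   consolidated = consolidated, clusters = clusters,
                   log = logline)
    if (!is.null(outdir)) persist_bundle(bundle, outdir)
    bundle
}

# Writes every table of a result bundle as TSV plus the config as YAML.
persist_bundle <- function(bundle, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(unclass(bundle$config), file.path(outdir, "config.yaml"))
    for (nm in names(bundle$analyses)) {
        an <- bundle$analyses[[nm]]
        write_counts_tsv(an$counts, file.path(outdir, paste0(nm, "_counts.tsv")),
                         extra = data.frame(keep = an$filter$keep))
        utils::write.table(as.data.frame(an$results),
                           file.path(outdir, paste0(nm, "_results.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(bundle$consolidated)) {
        utils::write.table(bundle$consolidated,
                           file.path(outdir, "consolidated.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (nrow(bundle$clusters$clusters)) {
        utils::write.table(bundle$clusters$clusters,
                           file.path(outdir, "clusters.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeLines(bundle$log, file.path(outdir, "pipeline.log"))
    invisible(outdir)
}
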
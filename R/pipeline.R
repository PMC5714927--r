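# Config-driven end-to-end runs: filter -> count -> annotate -> diff -> qc,
# with a run manifest and a text report.

default_params <- function() {
  list(
    adapter = "GATGAGTCTAGAA",
    min_length = 50L,       # minimum trimmed tag length [bp]
    mismatches = 1L,
    min_coverage = 2L,      # per-sample site coverage floor [reads]
    promoter_length = 1000L,
    alpha = 0.05,
    fc_threshold = 5,
    metric = "pearson",
    linkage = "average",
    seed = 1L
  )
}

#' Load a pipeline configuration from JSON or YAML
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` configuration file.
#' @return Configuration list (see [run_pipeline()]).
#' @export
load_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format: ", ext)
  }
}

validate_pipeline_config <- function(config) {
  problems <- character(0)
  if (is.null(config$genome)) problems <- c(problems, "missing 'genome'")
  if (!inherits(config$genome, "msap_genome") && is.character(config$genome) &&
      !file.exists(config$genome)) {
    problems <- c(problems, paste0("genome path not found: ", config$genome))
  }
  if (is.null(config$samples) || length(config$samples) == 0L ||
      is.null(names(config$samples))) {
    problems <- c(problems, "'samples' must be a named list (sample -> FASTQ path/reads)")
  } else {
    for (s in names(config$samples)) {
      v <- config$samples[[s]]
      if (is.character(v) && !all(file.exists(v))) {
        problems <- c(problems, paste0("sample '", s, "': FASTQ not found: ",
                                       paste(v[!file.exists(v)], collapse = ", ")))
      }
    }
  }
  for (f in c("gff", "go")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      problems <- c(problems, paste0("'", f, "' path not found: ", config[[f]]))
    }
  }
  if (!is.null(config$groups)) {
    if (length(config$groups) != 2L || is.null(names(config$groups))) {
      problems <- c(problems, "'groups' must name exactly two conditions")
    } else {
      missing <- setdiff(unlist(config$groups), names(config$samples))
      if (length(missing)) {
        problems <- c(problems, paste0("group sample(s) not defined: ",
                                       paste(missing, collapse = ", ")))
      }
    }
  }
  if (length(problems)) {
    stop("invalid pipeline config:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(config)
}

stage_msg <- function(stage, ...) {
  message(sprintf("[msapseq:%s] %s", stage, sprintf(...)))
}

#' Run the complete MSAP-Seq analysis pipeline
#'
#' Executes filter -> count -> annotate -> diff -> qc over a validated
#' configuration. Identical config and inputs yield byte-identical tables.
#'
#' @param config A list (or the result of [load_pipeline_config()]) with:
#'   `genome` (FASTA path or `msap_genome`); `samples` (named list: sample ->
#'   FASTQ path(s) or an in-memory read data frame); optional `gff` and `go`
#'   annotation paths; optional `groups` (named list of two conditions ->
#'   sample names; order = A then B); `replicated` (logical; default TRUE
#'   when both groups have >= 2 samples); `de_novo` (skip genome mapping and
#'   count by tag key); `params` overriding [pipeline defaults][run_pipeline]
#'   (adapter, min_length 50, mismatches 1, min_coverage 2, promoter_length
#'   1000, alpha 0.05, fc_threshold 5, metric, linkage, seed); `out_dir` to
#'   write tables.
#' @return A result bundle: list with `filter_stats`, `counts` (a
#'   `site_count_table`), `annotated`, `feature_dist`, `dms`, `tree`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  params <- utils::modifyList(default_params(), config$params %||% list())
  genome <- config$genome
  if (!inherits(genome, "msap_genome")) genome <- read_genome_fasta(genome)

  stage_msg("filter", "filtering %d sample(s)", length(config$samples))
  tag_sets <- list()
  filter_stats <- NULL
  for (s in names(config$samples)) {
    v <- config$samples[[s]]
    reads <- if (is.character(v)) {
      do.call(rbind, lapply(v, read_reads_fastq))
    } else v
    fl <- filter_reads(reads, adapter_query = params$adapter,
                       min_length = params$min_length,
                       max_mismatches = params$mismatches)
    tag_sets[[s]] <- fl$tags
    st <- cbind(sample = s, fl$stats)
    filter_stats <- rbind(filter_stats, st)
  }

  stage_msg("count", "assigning tags to CCGG sites")
  if (isTRUE(config$de_novo)) {
    counts <- denovo_tag_table(tag_sets)$table
  } else {
    sites <- find_sites(genome, restriction_enzyme("HpaII"))
    assignments <- lapply(tag_sets, map_tags_builtin, genome = genome,
                          ccgg_sites = sites)
    counts <- count_sites(assignments)
  }
  counts <- normalize_rpm(counts)
  counts <- apply_min_coverage(counts, params$min_coverage)

  annotated <- NULL
  feature_dist <- NULL
  if (!is.null(config$gff) && !isTRUE(config$de_novo)) {
    stage_msg("annotate", "classifying %d site(s)", nrow(counts$raw))
    ann <- read_annotation_gff3(config$gff, go_path = config$go)
    annotated <- classify_sites(rownames(counts$raw), ann,
                                promoter_length = params$promoter_length)
    feature_dist <- feature_distribution(annotated)
  }

  dms <- NULL
  if (!is.null(config$groups)) {
    ga <- config$groups[[1L]]
    gb <- config$groups[[2L]]
    sub_tab <- function(samples) {
      t <- site_count_table(counts$raw[, samples, drop = FALSE],
                            lib_sizes = counts$lib_sizes[samples])
      normalize_rpm(t)
    }
    replicated <- config$replicated %||% (length(ga) >= 2L && length(gb) >= 2L)
    stage_msg("diff", "%s differential calling: %s vs %s",
              if (replicated) "replicated" else "unreplicated",
              names(config$groups)[1L], names(config$groups)[2L])
    dms <- if (replicated) {
      call_dms_replicated(sub_tab(ga), sub_tab(gb), alpha = params$alpha)
    } else {
      call_dms_unreplicated(sub_tab(ga), sub_tab(gb),
                            fc_threshold = params$fc_threshold)
    }
  }

  tree <- NULL
  if (ncol(counts$raw) >= 3L) {
    stage_msg("qc", "clustering %d samples", ncol(counts$raw))
    tree <- hierarchical_cluster(
      sample_distance_matrix(counts, metric = params$metric),
      linkage = params$linkage)
  }

  manifest <- list(
    package = "msapseq",
    version = as.character(utils::packageVersion("msapseq")),
    params = params,
    samples = names(config$samples),
    de_novo = isTRUE(config$de_novo),
    groups = config$groups
  )
  bundle <- list(filter_stats = filter_stats, counts = counts,
                 annotated = annotated, feature_dist = feature_dist,
                 dms = dms, tree = tree, manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_count_table(counts, file.path(config$out_dir, "counts.tsv"))
    write.table(filter_stats, file.path(config$out_dir, "filter_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(dms)) {
      write.table(dms, file.path(config$out_dir, "dms.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write_dms_bed(dms[dms$significant, , drop = FALSE],
                    file.path(config$out_dir, "dms.bed"))
    }
    if (!is.null(annotated)) {
      write.table(annotated, file.path(config$out_dir, "annotated.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(tree)) write_newick(tree, file.path(config$out_dir, "tree.nwk"))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
               file.path(config$out_dir, "manifest.json"))
  }
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a pipeline result bundle as text
#'
#' @param bundle Result of [run_pipeline()].
#' @return Character vector of report lines (also printable with `cat`).
#' @export
run_report <- function(bundle) {
  lines <- c("MSAP-Seq pipeline report", "=======================")
  fs <- bundle$filter_stats
  lines <- c(lines, "", "Read filter funnel (per sample):")
  for (i in seq_len(nrow(fs))) {
    lines <- c(lines, sprintf(
      "  %s: %d reads -> %d with HpaII adapter -> %d with CGG -> %d length-pass (%.1f%% retained)",
      fs$sample[i], fs$input[i], fs$with_adapter[i], fs$with_cgg[i],
      fs$length_pass[i], 100 * fs$retained_fraction[i]))
  }
  cv <- bundle$counts
  per_sample_sites <- colSums(cv$raw > 0)
  lines <- c(lines, "", sprintf("CCGG sites in table: %d", nrow(cv$raw)),
             "Sites detected per sample:")
  lines <- c(lines, sprintf("  %s: %d", names(per_sample_sites),
                            per_sample_sites))
  if (!is.null(bundle$feature_dist)) {
    fd <- bundle$feature_dist
    lines <- c(lines, "", "Genomic feature distribution:")
    lines <- c(lines, sprintf("  %s: %d (%.1f%%)", fd$category, fd$count,
                              fd$percent))
  }
  if (!is.null(bundle$dms)) {
    sig <- bundle$dms[bundle$dms$significant, , drop = FALSE]
    if (nrow(sig) == 0L) {
      lines <- c(lines, "", "Differential methylation: zero DMS called")
    } else {
      lines <- c(lines, "", sprintf("Differential methylation: %d DMS", nrow(sig)),
                 sprintf("  new methylation: %d",
                         sum(sig$direction == "new_methylation", na.rm = TRUE)),
                 sprintf("  demethylation:   %d",
                         sum(sig$direction == "demethylation", na.rm = TRUE)),
                 sprintf("  qualitative (presence/absence): %d",
                         sum(sig$qualitative, na.rm = TRUE)))
    }
  }
  if (!is.null(bundle$tree)) {
    lines <- c(lines, "", "Sample clustering (newick):", paste0("  ", bundle$tree$newick))
  }
  lines
}
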
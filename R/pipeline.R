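# End-to-end orchestration: synth -> detect -> classify -> cluster ->
# date -> tree -> depth, with one global seed fanned out per stage, a
# manifest of every artifact written, and a reproducible run report.

pipeline_defaults <- list(
  seed = 1L, out_dir = "retrochrono_out",
  stages = "simulate,detect,classify,cluster,date,tree,depth",
  genome_fasta = "", reads_prefix = "",
  background_length = 200000L, n_families = 4L,
  copy_min = 2L, copy_max = 8L, ltr_length = 400L,
  internal_length = 3000L, age_min_my = 0, age_max_my = 2,
  solo_fraction = 0, fragment_fraction = 0,
  coverage = 5, read_length = 100L, error_rate = 0,
  min_ltr = 100L, max_ltr = 3500L, min_element = 1000L,
  max_element = 20000L, min_ltr_identity = 0.75,
  cluster_min_identity = 0.80, cluster_min_coverage = 0.50,
  clock_rate = 1.3e-8, correction = "jukes_cantor",
  dedupe_identity = 0.95, lib_min_length = 150L,
  max_mismatch_per_100bp = 2, top_n = 20L,
  reference_genome = "synthetic")

#' Assemble a pipeline configuration
#'
#' Starts from the package defaults and overrides the supplied keys.
#' Unknown keys are rejected. The configuration round-trips through
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param ... named overrides of the default keys
#' @return named list of class `pipeline_config`
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == "")))
    stop("all configuration entries must be named")
  unknown <- setdiff(names(over), names(pipeline_defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(pipeline_defaults, over)
  for (key in names(pipeline_defaults)) {
    tmpl <- pipeline_defaults[[key]]
    if (is.integer(tmpl)) cfg[[key]] <- as.integer(cfg[[key]])
    else if (is.numeric(tmpl)) cfg[[key]] <- as.numeric(cfg[[key]])
    else cfg[[key]] <- as.character(cfg[[key]])
  }
  structure(cfg, class = "pipeline_config")
}

#' Write / read a flat key-value configuration file
#'
#' @param config a `pipeline_config`
#' @param path file path
#' @export
write_pipeline_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, function(v) format(v, digits = 15),
                            character(1))), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^ *([^= ]+) *= *(.*)$", lines))
  bad <- which(lengths(kv) != 3)
  if (length(bad)) stop("malformed config line ", bad[1], ": ", lines[bad[1]])
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  do.call(pipeline_config, as.list(setNames(trimws(vals), keys)))
}

demo_family_specs <- function(cfg) {
  sfs <- rep(c("gypsy", "copia", "unclassified"),
             length.out = cfg$n_families)
  copies <- round(seq(cfg$copy_max, cfg$copy_min,
                      length.out = cfg$n_families))
  lapply(seq_len(cfg$n_families), function(i)
    family_spec(sprintf("FAM%02d", i), superfamily = sfs[i],
                ltr_length = cfg$ltr_length,
                internal_length = cfg$internal_length,
                copy_number = copies[i],
                age_dist = age_uniform(cfg$age_min_my * 1e6,
                                       cfg$age_max_my * 1e6),
                solo_fraction = cfg$solo_fraction,
                fragment_fraction = cfg$fragment_fraction))
}

pipe_log <- function(stage, msg, ...) {
  message(sprintf("[%s] %s", stage, sprintf(msg, ...)))
}

#' Run the full pipeline
#'
#' Executes the stages listed in `config$stages` in canonical order,
#' writing every artifact under `config$out_dir` plus a `manifest.tsv`
#' listing them. Identical configuration and seed reproduce the report
#' (and all text artifacts) exactly. A stage whose prerequisite outputs
#' are missing aborts with a stage-tagged error.
#'
#' @param config a [pipeline_config()]
#' @return a `run_report`: per-stage counts, the ranked family table, and
#'   the manifest
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- strsplit(config$stages, ",", fixed = TRUE)[[1]]
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  note <- function(p) manifest <<- c(manifest, p)
  counts <- list()

  genome <- NULL; reads <- NULL
  if ("simulate" %in% stages) {
    pipe_log("simulate", "building genome (%d families, %d b background)",
             config$n_families, config$background_length)
    genome <- build_genome(demo_family_specs(config),
                           background_length = config$background_length,
                           mutation_rate = config$clock_rate,
                           seed = config$seed)
    reads <- simulate_reads(genome, coverage = config$coverage,
                            read_length = config$read_length,
                            error_rate = config$error_rate,
                            seed = config$seed)
    write_fasta(c(synthetic = genome$sequence),
                file.path(out, "genome.fa")); note("genome.fa")
    for (p in write_truth(genome, out)) note(basename(p))
    write_fastq(reads, file.path(out, "reads"))
    note("reads_1.fq"); note("reads_2.fq")
    counts$planted <- nrow(genome$truth)
  } else if (nzchar(config$genome_fasta)) {
    sq <- read_fasta(config$genome_fasta)
    genome <- setNames(as.character(sq), names(sq))
  }

  elements <- NULL
  if ("detect" %in% stages) {
    if (is.null(genome))
      stop("[detect] no genome available: enable the simulate stage or ",
           "set genome_fasta")
    dc <- detector_config(min_ltr = config$min_ltr,
                          max_ltr = config$max_ltr,
                          min_element = config$min_element,
                          max_element = config$max_element,
                          min_ltr_identity = config$min_ltr_identity)
    elements <- find_intact_elements(genome, dc)
    elements <- remove_tandem_false_positives(elements, genome)
    pipe_log("detect", "%d intact elements", nrow(elements))
    gff3_write(elements_to_gff(elements), file.path(out, "elements.gff3"))
    note("elements.gff3")
    write_tsv(elements, file.path(out, "elements.tsv"))
    note("elements.tsv")
    counts$elements <- nrow(elements)
  }

  seqs <- NULL
  if (!is.null(elements) && nrow(elements) > 0)
    seqs <- element_sequences(elements, genome)

  if ("classify" %in% stages) {
    if (is.null(elements))
      stop("[classify] requires the detect stage")
    refs <- if (inherits(genome, "synthetic_genome"))
      domain_references(genome) else NULL
    if (is.null(refs) || length(refs) == 0) {
      pipe_log("classify", "no domain references; all unclassified")
      elements$superfamily <- rep("unclassified", nrow(elements))
    } else {
      for (i in seq_len(nrow(elements))) {
        hits <- scan_domains(seqs$internal[[i]], refs)
        elements$superfamily[i] <- classify_superfamily(hits)
        if (nrow(hits) > 0) {
          # direct repeats are strand-symmetric; the coding strand of the
          # domain hits orients the element
          elements$strand[i] <-
            names(sort(table(hits$strand), decreasing = TRUE))[1]
        }
      }
    }
    counts$superfamily <- as.list(table(elements$superfamily))
  }

  famset <- NULL
  if ("cluster" %in% stages) {
    if (is.null(elements)) stop("[cluster] requires the detect stage")
    famset <- cluster_families(
      elements, genome,
      clustering_config(config$cluster_min_identity,
                        config$cluster_min_coverage))
    famset <- name_and_rank_families(famset)
    pipe_log("cluster", "%d families", nrow(famset$families))
    write_tsv(famset$families, file.path(out, "families.tsv"))
    note("families.tsv")
    write_tsv(data.frame(element_id = names(famset$membership),
                         family_id = unname(famset$membership)),
              file.path(out, "membership.tsv"))
    note("membership.tsv")
    counts$families <- nrow(famset$families)
  }

  dates <- NULL
  if ("date" %in% stages) {
    if (is.null(elements)) stop("[date] requires the detect stage")
    dates <- date_elements(elements, genome,
                           clock_config(rate = config$clock_rate,
                                        correction = config$correction),
                           seqs = seqs)
    pipe_log("date", "%d/%d elements datable", sum(dates$datable),
             nrow(dates))
    write_tsv(dates, file.path(out, "dates.tsv")); note("dates.tsv")
    counts$datable <- sum(dates$datable)
    if (!is.null(famset)) {
      fa <- summarize_family_ages(dates, famset$membership)
      write_tsv(fa, file.path(out, "family_ages.tsv"))
      note("family_ages.tsv")
    }
  }

  if ("tree" %in% stages) {
    if (is.null(elements)) stop("[tree] requires the detect stage")
    refs <- if (inherits(genome, "synthetic_genome"))
      domain_references(genome) else NULL
    rt <- character(0)
    if (!is.null(refs) && "RT" %in% names(refs) && nrow(elements) > 0) {
      for (i in seq_len(nrow(elements))) {
        hits <- scan_domains(seqs$internal[[i]], refs["RT"])
        if (nrow(hits) == 1)
          rt[elements$element_id[i]] <- extract_rt(seqs$internal[[i]],
                                                   hits)$aa
      }
    }
    counts$rt_sequences <- length(rt)
    if (length(rt) >= 3) {
      aln <- align_center_star(rt, type = "protein")
      tree <- neighbor_joining(p_distance_matrix(aln))
      ape::write.tree(tree, file.path(out, "rt_tree.nwk"))
      note("rt_tree.nwk")
    } else {
      pipe_log("tree", "fewer than 3 RT sequences; tree skipped")
    }
  }

  depth <- NULL
  if ("depth" %in% stages) {
    if (is.null(elements)) stop("[depth] requires the detect stage")
    if (is.null(reads)) {
      if (!nzchar(config$reads_prefix))
        stop("[depth] no reads: enable the simulate stage or set ",
             "reads_prefix")
      reads <- read_fastq_pairs(paste0(config$reads_prefix, "_1.fq"),
                                paste0(config$reads_prefix, "_2.fq"))
    }
    seqs5 <- seqs$ltr5
    fam_of <- if (!is.null(famset)) famset$membership else
      setNames(elements$element_id, elements$element_id)
    lib <- build_ltr_library(seqs5, family = fam_of,
                             dedupe_identity = config$dedupe_identity,
                             min_length = config$lib_min_length)
    write_fasta(lib$reps, file.path(out, "ltr_library.fa"))
    note("ltr_library.fa")
    md <- genome_mean_depth(reads, genome_length = if (inherits(
      genome, "synthetic_genome")) nchar(genome$sequence) else
        sum(nchar(genome)))
    hits <- map_reads(reads, lib,
                      max_mismatch_per_100bp = config$max_mismatch_per_100bp)
    depth <- depth_profile(hits, lib, md)
    write_tsv(depth$per_family, file.path(out, "depth_by_family.tsv"))
    note("depth_by_family.tsv")
    counts$library_size <- length(lib$reps)
    counts$mapped_read_fraction <-
      length(unique(hits$read)) / attr(hits, "n_reads")
  }

  fam_table <- NULL
  if (!is.null(famset)) {
    fam_table <- make_family_table(famset, dates, depth,
                                   top_n = config$top_n)
    write_tsv(fam_table, file.path(out, "family_table.tsv"))
    note("family_table.tsv")
  }

  manifest <- sort(unique(manifest))
  write_tsv(data.frame(file = manifest), file.path(out, "manifest.tsv"))
  report <- structure(list(counts = counts, family_table = fam_table,
                           manifest = manifest, config = unclass(config)),
                      class = "run_report")
  jsonlite::write_json(
    list(counts = counts, manifest = manifest),
    file.path(out, "report.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  for (nm in names(x$counts)) {
    v <- x$counts[[nm]]
    if (is.list(v)) v <- paste(names(v), unlist(v), sep = "=",
                               collapse = " ")
    cat(sprintf("  %-22s %s\n", nm, paste(format(v), collapse = " ")))
  }
  if (!is.null(x$family_table)) {
    cat("  top families:\n")
    print(utils::head(x$family_table, 5))
  }
  invisible(x)
}

#' Ranked family summary table
#'
#' One row per family, descending by intact copy count (the family-set
#' ranking), carrying superfamily, copy class, mean insertion age (million
#' years) and normalized read depth where available.
#'
#' @param famset a ranked `family_set`
#' @param dates optional [date_elements()] output
#' @param depth optional `depth_profile`
#' @param top_n rows to keep (> 0; larger than the family count keeps all)
#' @return data.frame
#' @export
make_family_table <- function(famset, dates = NULL, depth = NULL,
                              top_n = 20L) {
  if (top_n <= 0) stop("top_n must be positive")
  fams <- famset$families
  tab <- data.frame(rank = fams$rank %||% seq_len(nrow(fams)),
                    family_id = fams$family_id,
                    superfamily = fams$superfamily,
                    n_intact = fams$n_intact,
                    copy_class = fams$copy_class %||%
                      rep(NA_character_, nrow(fams)),
                    stringsAsFactors = FALSE)
  tab$mean_age_my <- NA_real_
  if (!is.null(dates)) {
    sm <- summarize_family_ages(dates, famset$membership)
    tab$mean_age_my <- sm$mean[match(tab$family_id, sm$family_id)] / 1e6
  }
  tab$norm_depth <- NA_real_
  if (!is.null(depth)) {
    pf <- depth$per_family
    tab$norm_depth <- pf$norm_depth[match(tab$family_id, pf$family)]
  }
  tab <- tab[order(tab$rank), , drop = FALSE]
  rownames(tab) <- NULL
  utils::head(tab, top_n)
}

#' Command-line entry point
#'
#' Subcommands: `run` (full pipeline), `simulate`, `detect`, `date`,
#' `depth` -- all thin wrappers over [run_pipeline()] with the matching
#' stage subset. Arguments: `--config FILE`, `--seed N`, `--out DIR`, and
#' `key=value` overrides of any configuration key.
#'
#' @param args character vector, defaulting to the process arguments
#' @return the `run_report`, invisibly
#' @export
retro_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: retro-chrono <run|simulate|detect|date|depth>",
        "[--config FILE] [--seed N] [--out DIR] [key=value ...]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]; args <- args[-1]
  over <- list()
  cfg_file <- NULL
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--config") { cfg_file <- args[i + 1]; i <- i + 2 }
    else if (a == "--seed") { over$seed <- as.integer(args[i + 1]); i <- i + 2 }
    else if (a == "--out") { over$out_dir <- args[i + 1]; i <- i + 2 }
    else if (grepl("=", a, fixed = TRUE)) {
      kv <- strsplit(a, "=", fixed = TRUE)[[1]]
      over[[kv[1]]] <- paste(kv[-1], collapse = "=")
      i <- i + 1
    } else stop("unrecognized argument: ", a)
  }
  cfg <- if (is.null(cfg_file)) pipeline_config()
         else read_pipeline_config(cfg_file)
  stage_map <- list(
    run = "simulate,detect,classify,cluster,date,tree,depth",
    simulate = "simulate",
    detect = "simulate,detect",
    date = "simulate,detect,classify,cluster,date",
    depth = "simulate,detect,classify,cluster,depth")
  if (!cmd %in% names(stage_map)) stop("unknown subcommand: ", cmd)
  over$stages <- stage_map[[cmd]]
  cfg <- do.call(pipeline_config, utils::modifyList(unclass(cfg), over))
  invisible(run_pipeline(cfg))
}
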
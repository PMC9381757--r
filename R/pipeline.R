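## Config-driven orchestration: run the synthetic generators and all four
## analyses in dependency order, write every result as TSV, and record full
## provenance (config echo, config hash, package version).  Re-running with
## an identical config gives byte-identical numeric tables; only the
## provenance file carries a timestamp.

#' Default pipeline configuration
#'
#' The complete RunConfig with every tunable parameter at its default.
#' User configs (YAML) are validated against this template: unknown keys
#' are rejected, missing keys fall back to these defaults, and the merged
#' config is echoed into the provenance file of every run.
#'
#' @return nested named list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 20220816,
    stages = c("simulate", "pcc", "foci", "satellite", "quantify"),
    simulate = list(
      n_example_images = 1L,
      write_tiff = TRUE
    ),
    pcc = list(
      n_nuclei_per_mode = 12L,
      marker_name = "H3K27me3",
      n_chromocenters = 4L,
      noise_sd = 600,
      half_length_um = 2.5
    ),
    foci = list(
      n_nuclei = 20L,
      max_foci = 6L,
      focus_amplitude = 12000,
      noise_sd = 600,
      detection_k = 6,
      min_separation_um = 0.5
    ),
    satellite = list(
      n_reads = 2000L,
      read_length = 50L,
      satellite_fraction = 0.1,
      methylation_rate = 0.8,
      conversion_efficiency = 1
    ),
    quantify = list(
      n_per_group = 10L,
      marker_amplitude = 12000,
      amplitude_ratio = 0.24,
      xi_ratio = 0.35,
      noise_sd = 0
    )
  )
}

## Recursively merge a user config into the defaults, rejecting unknown keys.
.merge_config <- function(user, defaults, path = "") {
  .assert(is.list(user), sprintf("config section '%s' must be a mapping",
                                 path))
  unknown <- setdiff(names(user), names(defaults))
  .assert(length(unknown) == 0L,
          sprintf("unknown config key%s: %s",
                  if (length(unknown) > 1L) "s" else "",
                  paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                         collapse = ", ")))
  out <- defaults
  for (k in names(user)) {
    out[[k]] <- if (is.list(defaults[[k]])) {
      .merge_config(user[[k]], defaults[[k]], paste0(path, ".", k))
    } else {
      user[[k]]
    }
  }
  out
}

.config_md5 <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}

#' Run the full synthetic-to-tables pipeline
#'
#' Executes the requested stages in order on synthetic inputs with known
#' ground truth and writes one TSV per result table into `out_dir`:
#'
#' * `simulate`: example nucleus images (one per marker mode) as TIFF with
#'   a ground-truth sidecar TSV;
#' * `pcc`: per-chromocenter PCC records (`pcc_records.tsv`), group
#'   summaries (`pcc_summary.tsv`) and the violin-ready long table
#'   (`pcc_violin.tsv`), one group per marker mode;
#' * `foci`: per-nucleus focus records and the categorical proportion
#'   table;
#' * `satellite`: satellite-read percentage and bisulfite conversion from
#'   generated FASTQ files;
#' * `quantify`: per-nucleus intensity measurements for a control and a
#'   reduced-amplitude group plus the Mann-Whitney comparisons (whole
#'   nucleus and Xi region).
#'
#' Every run writes `provenance.yaml` with the merged config, its MD5 hash
#' and the package version.  A failing stage halts the run with the stage
#' name in the error; `provenance.yaml` then records the stages completed.
#'
#' @param config a config list, or the path of a YAML file validated
#'   against [default_pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with `config`, `outputs` (named file paths) and
#'   `tables` (the in-memory result tables).
#' @examples
#' \donttest{
#' cfg <- default_pipeline_config()
#' cfg$stages <- "pcc"
#' cfg$pcc$n_nuclei_per_mode <- 3L
#' res <- run_pipeline(cfg, tempfile("run"))
#' names(res$tables)
#' }
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = "chromoquant_run") {
  if (is.character(config) && length(config) == 1L) {
    .assert(file.exists(config), sprintf("no config file at '%s'", config))
    config <- yaml::read_yaml(config)
  }
  config <- .merge_config(config, default_pipeline_config())
  known <- c("simulate", "pcc", "foci", "satellite", "quantify")
  .assert(all(config$stages %in% known),
          sprintf("unknown stage(s): %s",
                  paste(setdiff(config$stages, known), collapse = ", ")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  tables <- list()
  done <- character(0)
  seed <- config$seed

  run_stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    res <- tryCatch(fn(), error = function(e) {
      .write_provenance(out_dir, config, done, incomplete = name)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    for (nm in names(res$files)) outputs[nm] <<- res$files[[nm]]
    for (nm in names(res$tables)) tables[[nm]] <<- res$tables[[nm]]
    done <<- c(done, name)
    invisible(NULL)
  }

  run_stage("simulate", function() {
    .stage_simulate(config, out_dir, .derive_seed(seed, 101))
  })
  run_stage("pcc", function() {
    .stage_pcc(config, out_dir, .derive_seed(seed, 202))
  })
  run_stage("foci", function() {
    .stage_foci(config, out_dir, .derive_seed(seed, 303))
  })
  run_stage("satellite", function() {
    .stage_satellite(config, out_dir, .derive_seed(seed, 404))
  })
  run_stage("quantify", function() {
    .stage_quantify(config, out_dir, .derive_seed(seed, 505))
  })

  .write_provenance(out_dir, config, done)
  invisible(list(config = config, outputs = outputs, tables = tables))
}

.write_provenance <- function(out_dir, config, done, incomplete = NULL) {
  prov <- list(
    package = "chromoquant",
    version = as.character(packageVersion("chromoquant")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_md5 = .config_md5(config),
    stages_completed = as.list(done),
    config = config
  )
  if (!is.null(incomplete)) prov$incomplete_stage <- incomplete
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
}

.stage_simulate <- function(config, out_dir, seed) {
  sc <- config$simulate
  files <- character(0)
  rows <- list()
  for (mode in c("colocalized", "cloudy", "diffuse")) {
    for (i in seq_len(sc$n_example_images)) {
      syn <- generate_nucleus_image(
        marker_mode = mode, marker_name = config$pcc$marker_name,
        noise_sd = config$pcc$noise_sd,
        n_chromocenters = config$pcc$n_chromocenters,
        seed = .derive_seed(seed, i * 7L + match(mode, c(
          "colocalized", "cloudy", "diffuse")))
      )
      if (isTRUE(sc$write_tiff)) {
        prefix <- file.path(out_dir, sprintf("sim_%s_%02d", mode, i))
        write_image_stack(syn$image, prefix)
        files[sprintf("sim_%s_%02d", mode, i)] <-
          paste0(prefix, "_stack.yaml")
      }
      tr <- syn$truth$foci
      tr$marker_mode <- mode
      tr$image <- sprintf("sim_%s_%02d", mode, i)
      rows[[length(rows) + 1L]] <- tr
    }
  }
  truth <- do.call(rbind, rows)
  f <- file.path(out_dir, "simulated_truth.tsv")
  .write_tsv(truth, f)
  files["simulated_truth"] <- f
  list(files = as.list(files), tables = list(simulated_truth = truth))
}

.stage_pcc <- function(config, out_dir, seed) {
  pc <- config$pcc
  records <- list()
  for (mode in c("colocalized", "cloudy", "diffuse")) {
    for (i in seq_len(pc$n_nuclei_per_mode)) {
      syn <- generate_nucleus_image(
        marker_mode = mode, marker_name = pc$marker_name,
        noise_sd = pc$noise_sd, n_chromocenters = pc$n_chromocenters,
        seed = .derive_seed(seed, i * 11L + 1000L * match(mode, c(
          "colocalized", "cloudy", "diffuse")))
      )
      ctr <- unlist(syn$truth$foci[1L, c("x_um", "y_um")])
      prof <- extract_profile(syn$image, ctr,
                              half_length = pc$half_length_um)
      seg <- delineate_chromocenter(prof)
      if (!seg$found || seg$end_index - seg$start_index < 2L) next
      records[[length(records) + 1L]] <- pcc_enrichment(
        prof, seg, pc$marker_name,
        metadata = list(chromocenter_id = sprintf("%s_%02d_cc1", mode, i),
                        nucleus_id = sprintf("%s_%02d", mode, i),
                        stage = "none", lineage = "none"))
      records[[length(records)]]$marker_mode <- mode
    }
  }
  rec <- do.call(rbind, records)
  summ <- summarize_pcc(rec, group_by = c("marker_mode", "marker"))
  f_rec <- file.path(out_dir, "pcc_records.tsv")
  f_sum <- file.path(out_dir, "pcc_summary.tsv")
  .write_tsv(rec, f_rec)
  .write_tsv(summ$summary, f_sum)
  f_violin <- export_violin_data(summ$long,
                                 file.path(out_dir, "pcc_violin.tsv"))
  list(files = list(pcc_records = f_rec, pcc_summary = f_sum,
                    pcc_violin = f_violin),
       tables = list(pcc_records = rec, pcc_summary = summ$summary,
                     pcc_violin = summ$long))
}

.stage_foci <- function(config, out_dir, seed) {
  fc <- config$foci
  counts <- .with_seed(.derive_seed(seed, 1),
                       sample.int(fc$max_foci + 1L, fc$n_nuclei,
                                  replace = TRUE) - 1L)
  fix <- generate_fish_image(n_foci_per_nucleus = counts,
                             focus_amplitude = fc$focus_amplitude,
                             noise_sd = fc$noise_sd,
                             seed = .derive_seed(seed, 2))
  md <- data.frame(nucleus_id = sprintf("nuc_%03d", seq_along(counts)),
                   stage = "E3.5", lineage = "EPI",
                   stringsAsFactors = FALSE)
  rec <- count_fish_foci(fix$image, fix$label_mask, metadata = md,
                         k = fc$detection_k,
                         min_separation_um = fc$min_separation_um)
  rec$true_n_foci <- counts
  prop <- bin_and_tabulate(rec)
  f_rec <- file.path(out_dir, "foci_records.tsv")
  f_prop <- file.path(out_dir, "foci_proportions.tsv")
  .write_tsv(rec, f_rec)
  .write_tsv(prop, f_prop)
  list(files = list(foci_records = f_rec, foci_proportions = f_prop),
       tables = list(foci_records = rec, foci_proportions = prop))
}

.stage_satellite <- function(config, out_dir, seed) {
  sc <- config$satellite
  fq <- file.path(out_dir, "satellite_reads.fastq")
  generate_fastq(fq, n_reads = sc$n_reads, read_length = sc$read_length,
                 satellite_fraction = sc$satellite_fraction,
                 seed = .derive_seed(seed, 1))
  chip <- count_satellite_reads(fq)
  fq_bs <- file.path(out_dir, "bisulfite_reads.fastq")
  generate_fastq(fq_bs, n_reads = sc$n_reads, read_length = sc$read_length,
                 satellite_fraction = sc$satellite_fraction,
                 bisulfite = TRUE, methylation_rate = sc$methylation_rate,
                 conversion_efficiency = sc$conversion_efficiency,
                 seed = .derive_seed(seed, 2))
  bis <- bisulfite_conversion(fq_bs)
  tab_chip <- as.data.frame(chip)
  tab_bis <- as.data.frame(bis)
  ## keep tables byte-reproducible across output directories
  tab_chip$file <- basename(tab_chip$file)
  tab_bis$file <- basename(tab_bis$file)
  f_chip <- file.path(out_dir, "satellite_assay.tsv")
  f_bis <- file.path(out_dir, "bisulfite_assay.tsv")
  .write_tsv(tab_chip, f_chip)
  .write_tsv(tab_bis, f_bis)
  list(files = list(satellite_assay = f_chip, bisulfite_assay = f_bis),
       tables = list(satellite_assay = tab_chip, bisulfite_assay = tab_bis))
}

.stage_quantify <- function(config, out_dir, seed) {
  qc <- config$quantify
  groups <- list(scramble = 1, knockdown = qc$amplitude_ratio)
  meas <- list()
  xi <- list()
  for (g in names(groups)) {
    for (i in seq_len(qc$n_per_group)) {
      q <- generate_quant_image(
        marker_amplitude = qc$marker_amplitude * groups[[g]],
        noise_sd = qc$noise_sd, xi = TRUE,
        xi_target_amplitude = qc$marker_amplitude *
          if (g == "scramble") 1 else qc$xi_ratio,
        seed = .derive_seed(seed, i + 100L * match(g, names(groups))))
      m <- measure_nucleus(q$image, q$mask, channels = c("DAPI", "marker"),
                           nucleus_id = sprintf("%s_%02d", g, i), group = g)
      meas[[length(meas) + 1L]] <- as.data.frame(m)
      r <- measure_region(q$image, "EZH2", q$mask, "XiTarget",
                          nucleus_id = sprintf("%s_%02d", g, i), group = g)
      xi[[length(xi) + 1L]] <- data.frame(
        nucleus_id = r$nucleus_id, group = g, region_id = r$region_id,
        n_pixels = r$n_pixels, total = r$total, normalized = r$normalized,
        stringsAsFactors = FALSE)
    }
  }
  meas <- do.call(rbind, meas)
  xi <- do.call(rbind, xi)
  a <- meas$norm_marker[meas$group == "scramble"]
  b <- meas$norm_marker[meas$group == "knockdown"]
  cmp <- mann_whitney(a, b, "scramble", "knockdown")
  cmp$measure <- "nucleus_marker"
  xa <- xi$normalized[xi$group == "scramble"]
  xb <- xi$normalized[xi$group == "knockdown"]
  cmp_xi <- mann_whitney(xa, xb, "scramble", "knockdown")
  cmp_xi$measure <- "xi_target"
  comparisons <- rbind(cmp, cmp_xi)
  f_meas <- file.path(out_dir, "nucleus_measurements.tsv")
  f_xi <- file.path(out_dir, "xi_measurements.tsv")
  f_cmp <- file.path(out_dir, "group_comparisons.tsv")
  .write_tsv(meas, f_meas)
  .write_tsv(xi, f_xi)
  .write_tsv(comparisons, f_cmp)
  list(files = list(nucleus_measurements = f_meas, xi_measurements = f_xi,
                    group_comparisons = f_cmp),
       tables = list(nucleus_measurements = meas, xi_measurements = xi,
                     group_comparisons = comparisons))
}

#' Export a violin-ready long-format PCC table
#'
#' One row per chromocenter with its group labels, consumable by any
#' plotting layer (e.g. `ggplot2::geom_violin`).  An empty input yields a
#' header-only file.
#'
#' @param long data frame as in the `long` element of [summarize_pcc()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
export_violin_data <- function(long, path) {
  .assert(is.data.frame(long), "long must be a data frame")
  .write_tsv(long, path)
  invisible(path)
}
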
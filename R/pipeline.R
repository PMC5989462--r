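# Build pipeline: INI-style configuration -> self-contained build
# directory with unified block files, analysis reports, plots and a
# manifest.  Multiple configurations create independent directories;
# re-running an unchanged configuration reproduces every file byte for
# byte (the manifest records md5 digests to make that checkable).

# minimal INI: [section] headers, key = value lines, '#'/';' comments
parse_ini <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  for (ln in seq_along(lines)) {
    s <- trimws(sub("[;#].*$", "", lines[ln]))
    if (!nzchar(s)) next
    if (grepl("^\\[.+\\]$", s)) {
      section <- sub("^\\[(.+)\\]$", "\\1", s)
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", s, fixed = TRUE)) {
      if (is.null(section)) {
        stop("config line ", ln, " before any [section]: ", s)
      }
      kv <- regmatches(s, regexec("^([^=]+)=(.*)$", s))[[1]]
      out[[section]][[trimws(kv[2])]] <- trimws(kv[3])
    } else {
      stop("unparseable config line ", ln, ": ", s)
    }
  }
  out
}

#' Read and validate a build configuration
#'
#' INI-style file with sections:
#' ```
#' [reference]
#' name = hg          # genome label
#' sizes = hg.sizes   # chrom.sizes path
#' genes = hg.bed     # optional BED6
#' cytoband = hg.cyto # optional cytoBandIdeo table
#'
#' [target:mm]
#' sizes = mm.sizes
#' chain = hg.mm.chain        # anchor source: chain file, OR
#' # tsv = anchors.tsv        #   generic/dialect anchor TSV, OR
#' # synteny = blocks.txt     #   imported third-party block table
#' # dialect = satsuma        #   dialect for tsv/synteny sources
#'
#' [params]
#' resolution = 150000
#' max_gap = 150000
#' min_anchor = 100
#'
#' [output]
#' dir = mybuild
#' ```
#' Relative paths are resolved against the configuration file's directory.
#'
#' @param path Configuration file.
#' @return List of class `"build_config"`.
#' @export
read_build_config <- function(path) {
  ini <- parse_ini(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^/", p)) p else file.path(base, p)
  }
  if (is.null(ini$reference)) stop("config missing [reference] section")
  for (key in c("name", "sizes")) {
    if (is.null(ini$reference[[key]])) {
      stop("config [reference] missing key '", key, "'")
    }
  }
  tnames <- grep("^target:", names(ini), value = TRUE)
  if (length(tnames) == 0L) stop("config has no [target:<name>] section")
  targets <- lapply(tnames, function(sec) {
    t <- ini[[sec]]
    name <- sub("^target:", "", sec)
    if (is.null(t$sizes)) stop("config [", sec, "] missing key 'sizes'")
    src <- intersect(c("chain", "tsv", "synteny"), names(t))
    if (length(src) != 1L) {
      stop("config [", sec, "] needs exactly one of chain/tsv/synteny")
    }
    list(name = name, sizes = resolve(t$sizes), source_kind = src,
         source = resolve(t[[src]]),
         dialect = if (is.null(t$dialect)) "generic" else t$dialect,
         genes = resolve(t$genes), cytoband = resolve(t$cytoband))
  })
  p <- ini$params
  params <- build_params(
    resolution = as.numeric(if (is.null(p$resolution)) 150000
                            else p$resolution),
    max_gap = as.numeric(if (is.null(p$max_gap)) {
      if (is.null(p$resolution)) 150000 else p$resolution
    } else p$max_gap),
    min_anchor = as.numeric(if (is.null(p$min_anchor)) 100 else p$min_anchor)
  )
  out_dir <- if (!is.null(ini$output$dir)) resolve(ini$output$dir) else {
    resolve("synteny_build")
  }
  paths <- c(ini$reference$sizes, vapply(targets, `[[`, "", "sizes"),
             vapply(targets, `[[`, "", "source"))
  paths <- vapply(as.list(paths), function(x) resolve(x), "")
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("config refers to missing file(s): ", paste(missing, collapse = ", "))
  }
  structure(list(
    reference = list(name = ini$reference$name,
                     sizes = resolve(ini$reference$sizes),
                     genes = resolve(ini$reference$genes),
                     cytoband = resolve(ini$reference$cytoband)),
    targets = targets, params = params, out_dir = out_dir
  ), class = "build_config")
}

#' Build a synteny database directory from a configuration
#'
#' Reads every input, builds one pairwise map per target (or imports it
#' for `synteny` sources), intersects the pairwise maps into a
#' multi-species map, writes unified block files, analysis reports and a
#' `manifest.json` with parameters and input/output digests.  Inputs are
#' copied under `inputs/` so the directory is self-contained.
#'
#' @param config A `"build_config"` or a path to one.
#' @param out_dir Optional override of the configured output directory.
#' @return The build directory path, invisibly.
#' @export
cmd_build <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_build_config(config)
  dir <- if (is.null(out_dir)) config$out_dir else out_dir
  dir.create(file.path(dir, "inputs"), showWarnings = FALSE,
             recursive = TRUE)
  ref_k <- read_chrom_sizes(config$reference$sizes,
                            genome = config$reference$name)
  genes <- if (!is.null(config$reference$genes)) {
    read_bed_genes(config$reference$genes)
  }
  cyto <- if (!is.null(config$reference$cytoband)) {
    read_cytoband(config$reference$cytoband)
  }
# inputs are copied under standardized names so the directory is
  # self-contained and later commands can locate them
  inputs <- c(stats::setNames(config$reference$sizes,
                              paste0(config$reference$name, ".sizes")),
              if (!is.null(config$reference$genes))
                c(genes.bed = config$reference$genes),
              if (!is.null(config$reference$cytoband))
                c(cytoband.tsv = config$reference$cytoband))
  pairwise <- list()
  tgt_karyos <- list()
  for (t in config$targets) {
    tgt_k <- read_chrom_sizes(t$sizes, genome = t$name)
    tgt_karyos[[t$name]] <- tgt_k
    inputs <- c(inputs,
                stats::setNames(c(t$sizes, t$source),
                                c(paste0(t$name, ".sizes"),
                                  paste0("source_", t$name, ".txt"))))
    m <- switch(t$source_kind,
      chain = build_pairwise(read_chain(t$source, tgt_k),
                             config$reference$name, t$name, config$params,
                             ref_karyotype = ref_k),
      tsv = build_pairwise(read_anchors_tsv(t$source, t$dialect),
                           config$reference$name, t$name, config$params,
                           ref_karyotype = ref_k),
      synteny = convert_third_party(t$source, t$dialect,
                                    config$reference$name, t$name,
                                    chrom_order = ref_k$chrom)
    )
    pairwise[[t$name]] <- m
  }
  for (i in seq_along(inputs)) {
    file.copy(inputs[[i]], file.path(dir, "inputs", names(inputs)[i]),
              overwrite = TRUE)
  }
  outputs <- character(0)
  for (nm in names(pairwise)) {
    f <- file.path(dir, sprintf("synteny_%s.txt", nm))
    write_unified(pairwise[[nm]], f)
    outputs <- c(outputs, f)
  }
  multi <- intersect_maps(unname(pairwise), config$params)
  f <- file.path(dir, "synteny_multi.txt")
  write_unified(multi, f)
  outputs <- c(outputs, f)
  # analysis reports per target
  for (nm in names(pairwise)) {
    m <- pairwise[[nm]]
    rep <- rearrangement_report(m)
    f <- file.path(dir, sprintf("chromosomes_%s.tsv", nm))
    write_report_tsv(rep, f); outputs <- c(outputs, f)
    f <- file.path(dir, sprintf("coverage_%s.tsv", nm))
    write_report_tsv(coverage_summary(m, ref_k), f); outputs <- c(outputs, f)
    if (!is.null(genes)) {
      f <- file.path(dir, sprintf("genes_%s.tsv", nm))
      write_report_tsv(classify_genes(genes, m, nm), f)
      outputs <- c(outputs, f)
    }
  }
  manifest <- list(
    reference = config$reference$name,
    targets = vapply(config$targets, `[[`, "", "name"),
    params = unclass(config$params),
    inputs = lapply(seq_along(inputs), function(i) {
      list(file = names(inputs)[i], md5 = unname(tools::md5sum(inputs[[i]])))
    }),
    outputs = lapply(outputs, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Convert a third-party synteny table to a unified block file
#'
#' @param input Third-party table path.
#' @param dialect Preset name or [table_dialect()].
#' @param reference,target Genome names.
#' @param out Output unified file path.
#' @return `out`, invisibly.
#' @export
cmd_convert <- function(input, dialect, reference, target, out) {
  write_unified(convert_third_party(input, dialect, reference, target), out)
  invisible(out)
}

# read the maps of a build directory back
read_build <- function(build_dir) {
  mf <- file.path(build_dir, "manifest.json")
  if (!file.exists(mf)) stop("not a build directory (no manifest.json): ",
                             build_dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  ref_k <- read_chrom_sizes(
    file.path(build_dir, "inputs", paste0(manifest$reference, ".sizes")),
    genome = manifest$reference)
  pairwise <- lapply(manifest$targets, function(nm) {
    read_unified(file.path(build_dir, sprintf("synteny_%s.txt", nm)))
  })
  names(pairwise) <- manifest$targets
  list(manifest = manifest, ref_karyotype = ref_k, pairwise = pairwise,
       multi = read_unified(file.path(build_dir, "synteny_multi.txt")))
}

#' Re-run the analyses of a built directory
#'
#' @param build_dir Directory written by [cmd_build()].
#' @param target Target name (default: all).
#' @return Named list of report data frames (also rewritten as TSV).
#' @export
cmd_analyze <- function(build_dir, target = NULL) {
  bd <- read_build(build_dir)
  targets <- if (is.null(target)) bd$manifest$targets else target
  unknown <- setdiff(targets, bd$manifest$targets)
  if (length(unknown)) stop("unknown target: ", paste(unknown, collapse = ", "))
  gf <- file.path(build_dir, "inputs", "genes.bed")
  genes <- if (file.exists(gf)) read_bed_genes(gf)
  out <- list()
  for (nm in targets) {
    m <- bd$pairwise[[nm]]
    m$chrom_order <- bd$ref_karyotype$chrom
    rep <- rearrangement_report(m)
    cov <- coverage_summary(m, bd$ref_karyotype)
    write_report_tsv(rep, file.path(build_dir,
                                    sprintf("chromosomes_%s.tsv", nm)))
    write_report_tsv(cov, file.path(build_dir,
                                    sprintf("coverage_%s.tsv", nm)))
    out[[nm]] <- list(chromosomes = rep, coverage = cov)
    if (!is.null(genes)) {
      gc <- classify_genes(genes, m, nm)
      write_report_tsv(gc, file.path(build_dir,
                                     sprintf("genes_%s.tsv", nm)))
      out[[nm]]$genes <- gc
    }
  }
  out
}

#' Render plots for a built directory
#'
#' @param build_dir Directory written by [cmd_build()].
#' @param type `"circos"` or `"linear"`.
#' @param ref_chrom,target Selection for linear plots.
#' @param options [plot_options()].
#' @return Paths of written SVG files.
#' @export
cmd_plot <- function(build_dir, type = c("circos", "linear"),
                     ref_chrom = NULL, target = NULL,
                     options = plot_options()) {
  type <- match.arg(type)
  bd <- read_build(build_dir)
  pd <- file.path(build_dir, "plots")
  dir.create(pd, showWarnings = FALSE)
  tgt_ks <- lapply(bd$manifest$targets, function(nm) {
    read_chrom_sizes(file.path(build_dir, "inputs",
                               paste0(nm, ".sizes")), genome = nm)
  })
  names(tgt_ks) <- bd$manifest$targets
  if (type == "circos") {
    svg <- render_circos(bd$multi, bd$ref_karyotype, tgt_ks,
                         options = options)
    save_plot(svg, file.path(pd, "circos"))
  } else {
    if (is.null(ref_chrom) || is.null(target)) {
      stop("linear plots need ref_chrom and target")
    }
    m <- bd$pairwise[[target]]
    if (is.null(m)) stop("unknown target: ", target)
    svg <- render_linear(m, ref_chrom, target, options = options,
                         ref_karyotype = bd$ref_karyotype,
                         tgt_karyotype = tgt_ks[[target]])
    save_plot(svg, file.path(pd, sprintf("linear_%s_%s", ref_chrom, target)))
  }
}

#' Export the static HTML site of a built directory
#'
#' @param build_dir Directory written by [cmd_build()].
#' @param options [plot_options()].
#' @return The site directory, invisibly.
#' @export
cmd_site <- function(build_dir, options = plot_options()) {
  bd <- read_build(build_dir)
  tgt_ks <- lapply(bd$manifest$targets, function(nm) {
    read_chrom_sizes(file.path(build_dir, "inputs",
                               paste0(nm, ".sizes")), genome = nm)
  })
  names(tgt_ks) <- bd$manifest$targets
  karyos <- c(stats::setNames(list(bd$ref_karyotype),
                              bd$manifest$reference), tgt_ks)
  export_site(bd$multi, karyos, out_dir = file.path(build_dir, "site"),
              options = options)
}
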
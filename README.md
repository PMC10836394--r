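# relmeta

Headless R tools for inspecting, scoring and filtering the metadata of a
RELION single-particle cryo-EM project.

During automated cryo-EM data collection, hundreds of movies per hour flow
through motion correction and CTF estimation, and a large fraction of them
are ultimately useless: too much beam-induced drift, poor CTF fits, or thick
or crystalline ice. RELION stores everything it knows about a project in
plain-text STAR files but offers little help in reading them back out.
`relmeta` implements the computational core that live and retrospective
metadata dashboards need — as plain R functions plus a small CLI — so that
facility operators and processing users can score, filter and follow a
project without a GUI:

* **STAR I/O** — a lossless parser/writer for RELION's STAR metadata
  format, exposing loop tables as typed data frames
  (`parse_star()`, `write_star()`, `get_table()`, `add_column()`).
* **Ice-quality scoring** — both vitreous and crystalline ice produce
  intensity maxima in the micrograph power spectrum between 3.6 and
  4 Å. The ice score of a micrograph is the mean rotationally averaged
  spectral signal over the spatial-frequency band

  $$s \;=\; \operatorname{mean}\bigl\{\,\bar P(f) \;:\; 1/4 \le f \le 1/3.6
  \ \text{Å}^{-1}\,\bigr\},$$

  where $\bar P(f)$ is the radial average of $|\mathcal{F}(I)|^2$. The
  score is dimensionless — a ranking proxy for ice thickness and
  crystalline contamination, not a physical thickness. It is computed
  either natively from MRC micrographs or from the radially averaged
  profile ("avrot") files that CTFFIND4 already writes, and appended to the
  metadata as `rlnMicrographIceThickness` (`ice_score()`,
  `score_micrographs()`).
* **Live filtering and lasso selection** — inclusive per-label
  `[min, max]` thresholds and simple-polygon selection over any two
  metadata axes, with STAR re-export that RELION can import back
  (`apply_thresholds()`, `lasso_select()`, `export_selection()`,
  `three_variable_view()`).
* **Pipeline graph** — the project job graph parsed from `pipeline.star`:
  jobs and data files as nodes, input/output relationships as edges, with
  induced job-to-job edges, deterministic topological order and per-job
  parameter retrieval (`parse_pipeline()`, `job_edges()`,
  `topological_order()`, `job_parameters()`).
* **Run tracking** — per-iteration series from `run_itNNN_optimiser/model`
  files (`ChangesOptimalClasses`, `CurrentResolution`, or any other
  label), class-distribution matrices, per-class model spectra
  (`GoldStandardFsc`, `SsnrMap`, ...), FSC threshold crossing at the
  gold-standard 0.143 criterion, rotation-tilt angular histograms and
  live backlog counts (`extract_series()`, `class_distribution()`,
  `model_spectra()`, `fsc_crossing()`, `angular_histogram()`,
  `job_backlog()`).
* **Previews** — an MRC reader/writer and percentile-normalized 8-bit PNG
  previews of micrographs and CTF images (`read_mrc()`,
  `normalize_to_8bit()`, `render_preview_pair()`).
* **Synthetic projects** — a fully deterministic generator of miniature
  RELION project trees (micrographs with controllable ice rings, avrot
  profiles, pipeline and job files, planted classification runs) used
  throughout the test suite (`fixture_spec()`, `make_project()`,
  `make_micrograph()`, `make_particles()`).

## Worked example

Simulate a small project, score its ice, and filter on accumulated motion —
either from R or through the installed `exec/relmeta` script:

```r
library(relmeta)
relmeta_main(c("simulate", "--out", "demo", "--seed", "42", "--n", "8"))
#> simulate: wrote 8-micrograph project to demo
relmeta_main(c("score-ice", "--project", "demo",
               "--mics", "demo/CtfFind/job003/micrographs_ctf.star",
               "--out", "demo/scored.star"))
#> score-ice: scored 8 micrograph(s) -> demo/scored.star

writeLines("rlnAccumMotionTotal - 30", "demo/thr.txt")
relmeta_main(c("filter", "--mics", "demo/scored.star",
               "--config", "demo/thr.txt", "--out", "demo/filtered"))
#> kept 5 discarded 3
relmeta_main(c("graph", "--project", "demo"))
#> CtfFind/job003/	External/job004/
#> Import/job001/	MotionCorr/job002/
#> MotionCorr/job002/	CtfFind/job003/

tab <- get_table(read_star("demo/scored.star"))
head(tab[, c("rlnAccumMotionTotal", "rlnCtfMaxResolution",
             "rlnMicrographIceThickness")], 4)
#>   rlnAccumMotionTotal rlnCtfMaxResolution rlnMicrographIceThickness
#> 1            38.47269            3.634654              6.343778e-05
#> 2            21.52991            3.072227              1.660000e-04
#> 3            21.88078            4.839424              1.690000e-04
#> 4            43.24390            4.388396              1.200000e-04
```

The ice scores are normalized band means (dimensionless; higher = more ice
signal); `filter` keeps rows satisfying every rule inclusively, so a
micrograph with exactly 30 Å of accumulated motion would be kept. The
`graph` command prints the induced producer→consumer job edges of the
project pipeline.

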
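# scmhand

Similarity analysis of handwriting exams for Parkinson's-disease screening.

Spiral and meander drawing tests are a standard paper-based probe for
Parkinsonian motor symptoms: the subject traces a printed template curve and
the quality of the trace carries the diagnostic signal. `scmhand` automates
the analysis of scanned exams for researchers working on handwriting-based
screening. It segments each scan into the printed **exam template (ET)** and
the **handwritten trace (HT)**, quantifies how similar the two layers are,
and classifies subjects as control (CG) or patient (PG).

## Method

The core descriptor is a two-image **structural co-occurrence matrix**: for
a pixel-aligned image pair $(f, g)$ quantized to $N$ gray levels,

$$ m_{ij} = \frac{\#\{p : Q(f)(p) = i,\; Q(g)(p) = j\}}{\#p}, $$

a normalized joint histogram whose shape encodes the structural similarity
of the pair. Eight scalar attributes summarize $M = (m_{ij})$ and its row /
column marginals $P^r, P^c$: correlation (COR), inverse difference moment
(IDM), entropy (ENT), chi-square distance of the observed diagonal from the
row marginal (CSD), quadrant chi-square ratio (CSR), mean absolute
difference ratio of the marginal dispersions (MDR), Kullback–Leibler
divergence $D_{KL}(P^c \| P^r)$, and complementary absolute difference
(CAD). Any of three image pairs can feed the matrix: exam↔trace (`a_c`),
exam↔template (`a_b`), or trace↔template (`c_b`) — the last being the
direct "how well did the pen follow the print" comparison.

The package also implements the nine classical radius-profile attributes
(RMS radial deviation, extreme and standard deviation of
$r^i_{HT} - r^i_{ET}$, mean relative tremor, ET radius extremes, HT radius
sd, difference sign changes) as a reproducible baseline, and three
classifiers behind one contract: Gaussian Naive Bayes, an RBF-SVM with
validation-split hyperparameter search, and a from-scratch supervised
**Optimum-Path Forest** (prototypes = endpoints of inter-class MST edges,
path-max competition, Euclidean arcs). Evaluation is Monte-Carlo
cross-validation: repeated stratified 50/25/25 splits with accuracy
reported as mean ± sd.

Clinical scan collections are not bundled; a parametric generator renders
labeled synthetic exams (template + trace with sinusoidal tremor of chosen
amplitude, hand jitter, and scan-acquisition nuisances) so the entire
pipeline is testable end to end.

## Worked example

```r
library(scmhand)

exam_dir <- file.path(tempdir(), "exams")
manifest <- generate_dataset(n_cg = 12, n_pg = 28, format = "spiral",
                             master_seed = 7, out_dir = exam_dir)
features <- extract_features(manifest, image_dir = exam_dir,
                             combination = "c_b", features = "scm")
head(round(features[, c("cor", "idm", "ent", "mdr", "cad")], 3), 4)
#>      cor   idm   ent   mdr   cad
#> 1 -0.060 0.873 0.697 0.244 0.814
#> 2 -0.061 0.872 0.700 0.248 0.815
#> 3 -0.060 0.873 0.695 0.240 0.814
#> 4 -0.061 0.872 0.701 0.249 0.815

report <- run_experiment(features, classifiers = c("nb", "svm", "opf"),
                         n_runs = 20, seed = 42)
report
#> Repeated stratified-split evaluation (20 runs, 40 samples)
#>   nb   accuracy 100.00% +/- 0.00%
#>   svm  accuracy 100.00% +/- 0.00%
#>   opf  accuracy 100.00% +/- 0.00%
```

The first rows are control subjects: their traces sit almost on the
template, so CAD and MDR are high and stable. Patients' 6-px tremor pushes
trace ink off the printed curve, shifting every attribute; on this clean
synthetic benchmark the classes separate perfectly (a shuffled-label
control collapses to the 70% majority rate, so the signal is real).

Tremor magnitude itself is recovered by the baseline attributes:

```r
ex <- synthesize_exam(template_spec("spiral"), subject_spec("PG", seed = 1))
seg <- segment_exam(ex$exam)
p_et <- radius_profile(seg$b)
p_ht <- radius_profile(seg$c, center = p_et$center)
round(baseline_features(p_ht, p_et)$rms, 2)
#> [1] 5.31
```

— an RMS radial deviation of a few pixels, on the order of the subject's
6-px tremor amplitude (a pure 6-px sine would give $6/\sqrt{2} \approx
4.24$ on ground-truth masks; segmentation adds some noise).

A thin command-line front end over the same functions is installed at
`inst/cli/scmhand` (`generate`, `segment`, `features`, `experiment`,
`compare`).

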
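# structatlas

DNA sequence is usually read as text, but the double helix also has local
*structure* — how easily it melts, how willingly it wraps around
nucleosomes, how intrinsically curved it is — and these properties are
computable directly from sequence. `structatlas` computes seven windowed
structural-property tracks from a raw DNA sequence and renders them as a
fixed-width, multi-lane linear **structural atlas**, the visualisation style
used for large loci such as the ~5 Mbp MHC/HLA region, where a whole
haplotype is summarised at roughly 2 kbp per pixel and individual genes are
re-plotted at a few bp per pixel. It is aimed at genome biologists who want
a structural overview of a long haplotype or locus, and at anyone who needs
the underlying tracks in genome-browser formats.

## The tracks

For a sequence $s$ of length $L$ (coordinates 0-based half-open,
sliding windows of width $w$ reported at window centres):

* **Stacking energy** — mean dinucleotide base-stacking energy
  $\frac{1}{w}\sum_i E(s_i s_{i+1})$ in kcal/mol (Ornstein et al. 1978).
  Values near zero mark DNA that melts easily.
* **Position preference** — mean trinucleotide nucleosome position
  preference (Satchwell et al. 1986). Low values suggest DNA that resists
  nucleosome wrapping: candidate open chromatin.
* **Curvature** — magnitude of the vector sum of dinucleotide wedge angles
  accumulated with helical twist over a 21-bp window (Bolshoy et al. 1991),
  in degrees per bp step; phased A-tracts score high.
* **GC skew** — $(G - C)/(G + C)$ per window (default 10,000 bp).
* **AT content** — $(A + T)/w$, window defaulting to 0.1% of the plotted
  length.
* **Direct / inverted repeats** — for each 100-bp query window, the best
  ungapped identity against every other window of the sequence (direct) or
  of its reverse complement (inverted), excluding self-overlap, binned
  0–9: bin 9 means >90% identity, bin 0 <10%. The first value sits at
  50 bp and the last within 50 bp of the end.

An atlas stacks these lanes (plus a strand-separated gene lane from GFF3 or
GenBank annotations) into one image of fixed pixel width (default 2,500),
so the resolution in bp/pixel is `length / width` — 4,930,000 bp at
2,500 px is 1972 bp/pixel. Gene zooms drop GC skew, add the curvature
lane, shade introns, and orientation-normalise minus-strand genes to read
5′→3′.

## Worked example

```r
library(structatlas)

recipe <- fixture_recipe(20000, seed = 42, id = "toy", blocks = list(
  block("planted_direct_repeat", start = 15000, len = 100, src_start = 2000),
  block("at_rich", start = 8000, len = 500, p = 0.95)))
dna <- make_sequence(recipe)

rt <- repeat_track(dna, strand = "direct")
dplyr::filter(rt, value >= 9)
#> # A tibble: 2 × 4
#>     pos value best_identity match_start
#>   <int> <dbl>         <dbl>       <int>
#> 1  2050     9             1       15000
#> 2 15050     9             1        2000
```

The planted 100-bp duplicate is recovered at bin 9 at both loci — window
centres 2,050 and 15,050 bp — each pointing at the other as its best match.

```r
atlas <- build_atlas(dna, spec = atlas_spec(width_px = 1000),
                     windows = list(gc_skew = list(window = 2000)))
glance(atlas)
#> # A tibble: 1 × 6
#>   seq_id region_start region_end n_lanes width_px resolution_bp_per_px
#> 1 toy               0      20000       7     1000                   20
tidy(atlas)
#> # A tibble: 6 × 9
#>   track               seq_id window  step units       n n_missing    mean     sd
#> 1 stacking_energy     toy       101     1 kcal/mol 19899        0 -8.02   0.451
#> 2 position_preference toy       101     1 dimens…  19898        0  0.141  0.0171
#> 3 direct_repeats      toy       100   100 bin        200        0  4.08   0.538
#> 4 inverted_repeats    toy       100   100 bin        200        0  4.03   0.157
#> 5 gc_skew             toy      2000     1 ""       18001        0 -0.0201 0.0309
#> 6 at_content          toy        20     1 ""       19981        0  0.512  0.129

render_atlas(atlas, "toy_atlas.png")   # image + toy_atlas.json sidecar
autoplot(atlas)                        # same figure as a ggplot/patchwork
write_track(rt, "direct_repeats.bed", "bed")
```

At 1,000 px the 20-kb sequence plots at 20 bp/pixel; the sidecar JSON
records that resolution and every lane's mean/SD/window/step. The mean
direct-repeat bin of ~4 is what unrelated random windows of this length
score; the planted duplicate stands out at bin 9.

## Command line

```sh
inst/cli/structatlas atlas   -i seq.fasta -a genes.gff3 -o out/ --width-px 2500
inst/cli/structatlas zoom    -i seq.fasta -a genes.gff3 --gene HLA-A --flank 5000 -o out/
inst/cli/structatlas tracks  -i seq.fasta --track gc_skew --window 10000 --format bedgraph -o out/
inst/cli/structatlas compare -i hapA.fasta hapB.fasta -o out/
```

`atlas` writes the PNG, the JSON sidecar, five bedGraph value tracks and
two BED repeat tracks; `compare` stacks several inputs at a shared pixel
width and reports each input's own bp/pixel resolution.

## References

* Ornstein RL, Rein R, Breen DL, MacElroy RD (1978) *Biopolymers* 17:2341–2360.
* Satchwell SC, Drew HR, Travers AA (1986) *J Mol Biol* 191:659–675.
* Bolshoy A, McNamara P, Harrington RE, Trifonov EN (1991) *PNAS* 88:2312–2316.
* Kabsch W, Sander C, Trifonov EN (1982) *Nucleic Acids Res* 10:1097–1104.
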
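# Demo configuration: a 10-Mb hybrid chromosome with a 2-Mb switching
# (late) domain whose allele 1 can be advanced, across a 4-point inducer
# dose series with transcription-coupled advances.
outdir: allelert_demo
seed: 42
genome:
  chromosomes:
    - {name: chr1, length: 10000000}
  snp_spacing_mean: 150
  read_length: 100
domains:
  - {chrom: chr1, start: 0,       end: 3000000,  class: CE}
  - {chrom: chr1, start: 3000000, end: 4000000,  class: CL}
  - {chrom: chr1, start: 4000000, end: 6000000,  class: switching}
  - {chrom: chr1, start: 6000000, end: 8000000,  class: CL}
  - {chrom: chr1, start: 8000000, end: 10000000, class: CE}
advance_domain: {chrom: chr1, start: 4000000, end: 6000000}
allelic_offset: 0.1
repliseq:
  depth_per_fraction: 62
  n_replicates: 2
  bin_size: 50000
  k: 2
  n_permutations: 200
display:
  enabled: true
  bin_size: 5000
  span_bp: 300000
  target_halfrange: 3
genes:
  - {gene: Target, chrom: chr1, start: 4800000, end: 4916000, strand: "+"}
target_gene: Target
bruseq:
  library_scale: 1
  n_replicates: 2
  library_size: 1000000
conditions:
  - {label: dox0,   covariate: 0,   advance_delta: 0,    target_rate: 0}
  - {label: dox0.5, covariate: 0.5, advance_delta: 0.4,  target_rate: 40}
  - {label: dox1,   covariate: 1,   advance_delta: 0.7,  target_rate: 80}
  - {label: dox2,   covariate: 2,   advance_delta: 0.8,  target_rate: 100}
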
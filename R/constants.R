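# Reference genome geometry for the synthetic bin map (GRCh37 primary
# assembly lengths, rounded to the bp). Only relative sizes matter: autosomal
# read mass is apportioned by length.
.CHROM_LENGTHS <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
  chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
  chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
  chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566
)

# Approximate genome-wide GC fraction per chromosome; drives the synthetic
# per-bin GC values (gene-dense chr19 is GC-rich, chr4/13/X/Y GC-poor).
.CHROM_GC <- c(
  chr1 = 0.417, chr2 = 0.402, chr3 = 0.397, chr4 = 0.382, chr5 = 0.395,
  chr6 = 0.396, chr7 = 0.407, chr8 = 0.401, chr9 = 0.413, chr10 = 0.415,
  chr11 = 0.415, chr12 = 0.408, chr13 = 0.385, chr14 = 0.408, chr15 = 0.422,
  chr16 = 0.447, chr17 = 0.455, chr18 = 0.398, chr19 = 0.483, chr20 = 0.441,
  chr21 = 0.408, chr22 = 0.479, chrX = 0.395, chrY = 0.392
)

.AUTOSOMES <- paste0("chr", 1:22)
.SEX_CLASSES <- c("FF", "FM", "MM")
.CHORIONICITY_LEVELS <- c("DCDA", "MCDA", "MCMA", "unknown")
.MONOCHORIONIC <- c("MCDA", "MCMA")
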
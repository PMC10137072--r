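term	category	whole_word_only	source_group
polymerase chain reaction	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
pcr	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
rt-pcr	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
qpcr	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
genome-wide association	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
genome-wide	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
gwas	DNA_RNA	TRUE	Genomics and Nucleic Acid Analysis
genotyping	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
genotype	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
sequencing	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
sequenced	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
northern blot	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
southern blot	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
microarray	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
in situ hybridization	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
hybridization	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
exon	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
intron	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
mutation	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
nucleotide	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
polymorphism	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
snp	DNA_RNA	TRUE	Genomics and Nucleic Acid Analysis
allele	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
gene	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
genomic	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
genome	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
transcriptomics	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
transcriptome	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
transcription	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
transcript	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
mrna	DNA_RNA	TRUE	Genomics and Nucleic Acid Analysis
dna	DNA_RNA	TRUE	Genomics and Nucleic Acid Analysis
rna	DNA_RNA	TRUE	Genomics and Nucleic Acid Analysis
cdna	DNA_RNA	TRUE	Genomics and Nucleic Acid Analysis
sirna	DNA_RNA	TRUE	Genomics and Nucleic Acid Analysis
crispr	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
knockout	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
knockdown	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
plasmid	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
primer	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
oligonucleotide	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
replication	DNA_RNA	FALSE	Genomics and Nucleic Acid Analysis
western blot	PROTEIN	FALSE	Immunoanalytical methods
immunoblot	PROTEIN	FALSE	Immunoanalytical methods
sds-page	PROTEIN	FALSE	Proteomics
elisa	PROTEIN	TRUE	Immunoanalytical methods
immunoassay	PROTEIN	FALSE	Immunoanalytical methods
radioimmunoassay	PROTEIN	FALSE	Immunoanalytical methods
ria	PROTEIN	TRUE	Immunoanalytical methods
immunoprecipitation	PROTEIN	FALSE	Immunoanalytical methods
immunohistochemistry	PROTEIN	FALSE	Immunoanalytical methods
immunofluorescence	PROTEIN	FALSE	Immunoanalytical methods
immunostaining	PROTEIN	FALSE	Immunoanalytical methods
antibody	PROTEIN	FALSE	Immunoanalytical methods
antibodies	PROTEIN	FALSE	Immunoanalytical methods
monoclonal	PROTEIN	FALSE	Immunoanalytical methods
polyclonal	PROTEIN	FALSE	Immunoanalytical methods
mass spectrometry	PROTEIN	FALSE	Proteomics
proteomics	PROTEIN	FALSE	Proteomics
proteomic	PROTEIN	FALSE	Proteomics
proteome	PROTEIN	FALSE	Proteomics
peptide	PROTEIN	FALSE	Proteomics
protein	PROTEIN	FALSE	Proteomics
proteolytic	PROTEIN	FALSE	Enzymatic methods
enzyme assay	PROTEIN	FALSE	Enzymatic methods
enzyme activity	PROTEIN	FALSE	Enzymatic methods
enzymatic assay	PROTEIN	FALSE	Enzymatic methods
kinase assay	PROTEIN	FALSE	Enzymatic methods
flow cytometry	PROTEIN	FALSE	Immunoanalytical methods
affinity chromatography	PROTEIN	FALSE	Proteomics
electrophoresis	PROTEIN	FALSE	Proteomics
metabolomics	METABOLITE	FALSE	Metabolomics
metabolomic	METABOLITE	FALSE	Metabolomics
metabolome	METABOLITE	FALSE	Metabolomics
metabolite	METABOLITE	FALSE	Metabolomics
lipidomics	METABOLITE	FALSE	Lipidomics
lipidomic	METABOLITE	FALSE	Lipidomics
lipidome	METABOLITE	FALSE	Lipidomics
lipids	METABOLITE	FALSE	Lipidomics
lipid droplets	METABOLITE	FALSE	Lipidomics
lipid metabolism	METABOLITE	FALSE	Lipidomics
fatty acid	METABOLITE	FALSE	Lipidomics
triglyceride	METABOLITE	FALSE	Lipidomics
cholesterol	METABOLITE	FALSE	Lipidomics
sphingolipid	METABOLITE	FALSE	Lipidomics
ceramide	METABOLITE	FALSE	Lipidomics
carbohydrate	METABOLITE	FALSE	Glycomics
glycan	METABOLITE	FALSE	Glycomics
glycomics	METABOLITE	FALSE	Glycomics
glycolipid	METABOLITE	FALSE	Glycomics
glycosaminoglycan	METABOLITE	FALSE	Glycomics
gag	METABOLITE	TRUE	Glycomics
hplc	METABOLITE	FALSE	Metabolomics
gas chromatography	METABOLITE	FALSE	Metabolomics
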
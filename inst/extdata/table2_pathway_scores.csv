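pathway,score_rna,score_prot,overall,category
EIF2 Signaling,0.509,5.84,6.349,Growth
Regulation of eIF4 and p70S6K Signaling,0.209,5.53,5.739,Growth
tRNA Charging,1.57,3.87,5.44,Growth
CD28 Signaling in T Helper Cells,1.17,3.47,4.64,Immune
Integrin Signaling,0.527,3.64,4.167,Migration
fMLP Signaling in Neutrophils,0.471,3.56,4.031,Immune
Actin Nucleation by ARP-WASP Complex,0.62,3.4,4.02,Migration
Role of PKR in Interferon Induction and Antiviral Response,1.51,2.31,3.82,Immune
IL-17A Signaling in Fibroblasts,3.57,0.198,3.768,Immune
IL-6 Signaling,2.24,1.37,3.61,Immune
Regulation of IL-2 Expr in Activated and Anergic T Lymphocytes,2.66,0.732,3.392,Immune
Actin Cytoskeleton Signaling,0.756,2.58,3.336,Immune
RhoGDI Signaling,0.26,3.01,3.27,Migration
Acute Phase Response Signaling,1.18,2.03,3.21,Immune
Ephrin Receptor Signaling,0.209,3,3.209,Migration
Superpathway of Cholesterol Biosynthesis,2.94,0.198,3.138,Growth
Dendritic Cell Maturation,0.209,2.86,3.069,Immune
JAK/Stat Signaling,1.3,1.72,3.02,Growth
PI3K Signaling in B Lymphocytes,2.81,0.198,3.008,Immune
Rac Signaling,0.514,2.49,3.004,Migration
PKCtheta Signaling in T Lymphocytes,1.64,1.35,2.99,Immune
mTOR Signaling,0.209,2.76,2.969,Growth
PPAR Signaling,2.28,0.665,2.945,Growth
CD27 Signaling in Lymphocytes,2.73,0.198,2.928,Immune
4-1BB Signaling in T Lymphocytes,2.72,0.198,2.918,Immune
Protein Ubiquitination Pathway,0.549,2.33,2.879,Growth
EGF Signaling,0.979,1.88,2.859,Growth
VEGF Signaling,0.209,2.65,2.859,Growth
Signaling by Rho Family GTPases,0.403,2.44,2.843,Growth
PDGF Signaling,1.19,1.65,2.84,Growth
Selenocysteine Biosynthesis II (Archaea and Eukaryotes),1.02,1.82,2.84,Growth
Oncostatin M Signaling,0.36,2.47,2.83,Immune
Cdc42 Signaling,0.603,2.16,2.763,Migration
Fatty Acid beta-oxidation I,0.209,2.52,2.729,Growth
Estrogen-Dependent Breast Cancer Signaling,0.861,1.78,2.641,Growth
Role of NFAT in Regulation of the Immune Response,0.71,1.93,2.64,Immune
IL-17 Signaling,1.86,0.708,2.568,Immune
Th1 Pathway,0.209,2.32,2.529,Immune
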
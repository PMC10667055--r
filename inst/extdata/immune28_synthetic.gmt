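Activated B cell	SYNTHETIC placeholder genes for testing only	IMMSYN01_01	IMMSYN01_02	IMMSYN01_03	IMMSYN01_04	IMMSYN01_05	IMMSYN01_06	IMMSYN01_07	IMMSYN01_08	IMMSYN01_09	IMMSYN01_10	IMMSYN01_11	IMMSYN01_12	IMMSYN01_13	IMMSYN01_14	IMMSYN01_15
Activated CD4 T cell	SYNTHETIC placeholder genes for testing only	IMMSYN02_01	IMMSYN02_02	IMMSYN02_03	IMMSYN02_04	IMMSYN02_05	IMMSYN02_06	IMMSYN02_07	IMMSYN02_08	IMMSYN02_09	IMMSYN02_10	IMMSYN02_11	IMMSYN02_12	IMMSYN02_13	IMMSYN02_14	IMMSYN02_15
Activated CD8 T cell	SYNTHETIC placeholder genes for testing only	IMMSYN03_01	IMMSYN03_02	IMMSYN03_03	IMMSYN03_04	IMMSYN03_05	IMMSYN03_06	IMMSYN03_07	IMMSYN03_08	IMMSYN03_09	IMMSYN03_10	IMMSYN03_11	IMMSYN03_12	IMMSYN03_13	IMMSYN03_14	IMMSYN03_15
Activated dendritic cell	SYNTHETIC placeholder genes for testing only	IMMSYN04_01	IMMSYN04_02	IMMSYN04_03	IMMSYN04_04	IMMSYN04_05	IMMSYN04_06	IMMSYN04_07	IMMSYN04_08	IMMSYN04_09	IMMSYN04_10	IMMSYN04_11	IMMSYN04_12	IMMSYN04_13	IMMSYN04_14	IMMSYN04_15
CD56bright natural killer cell	SYNTHETIC placeholder genes for testing only	IMMSYN05_01	IMMSYN05_02	IMMSYN05_03	IMMSYN05_04	IMMSYN05_05	IMMSYN05_06	IMMSYN05_07	IMMSYN05_08	IMMSYN05_09	IMMSYN05_10	IMMSYN05_11	IMMSYN05_12	IMMSYN05_13	IMMSYN05_14	IMMSYN05_15
CD56dim natural killer cell	SYNTHETIC placeholder genes for testing only	IMMSYN06_01	IMMSYN06_02	IMMSYN06_03	IMMSYN06_04	IMMSYN06_05	IMMSYN06_06	IMMSYN06_07	IMMSYN06_08	IMMSYN06_09	IMMSYN06_10	IMMSYN06_11	IMMSYN06_12	IMMSYN06_13	IMMSYN06_14	IMMSYN06_15
Central memory CD4 T cell	SYNTHETIC placeholder genes for testing only	IMMSYN07_01	IMMSYN07_02	IMMSYN07_03	IMMSYN07_04	IMMSYN07_05	IMMSYN07_06	IMMSYN07_07	IMMSYN07_08	IMMSYN07_09	IMMSYN07_10	IMMSYN07_11	IMMSYN07_12	IMMSYN07_13	IMMSYN07_14	IMMSYN07_15
Central memory CD8 T cell	SYNTHETIC placeholder genes for testing only	IMMSYN08_01	IMMSYN08_02	IMMSYN08_03	IMMSYN08_04	IMMSYN08_05	IMMSYN08_06	IMMSYN08_07	IMMSYN08_08	IMMSYN08_09	IMMSYN08_10	IMMSYN08_11	IMMSYN08_12	IMMSYN08_13	IMMSYN08_14	IMMSYN08_15
Effector memory CD4 T cell	SYNTHETIC placeholder genes for testing only	IMMSYN09_01	IMMSYN09_02	IMMSYN09_03	IMMSYN09_04	IMMSYN09_05	IMMSYN09_06	IMMSYN09_07	IMMSYN09_08	IMMSYN09_09	IMMSYN09_10	IMMSYN09_11	IMMSYN09_12	IMMSYN09_13	IMMSYN09_14	IMMSYN09_15
Effector memory CD8 T cell	SYNTHETIC placeholder genes for testing only	IMMSYN10_01	IMMSYN10_02	IMMSYN10_03	IMMSYN10_04	IMMSYN10_05	IMMSYN10_06	IMMSYN10_07	IMMSYN10_08	IMMSYN10_09	IMMSYN10_10	IMMSYN10_11	IMMSYN10_12	IMMSYN10_13	IMMSYN10_14	IMMSYN10_15
Eosinophil	SYNTHETIC placeholder genes for testing only	IMMSYN11_01	IMMSYN11_02	IMMSYN11_03	IMMSYN11_04	IMMSYN11_05	IMMSYN11_06	IMMSYN11_07	IMMSYN11_08	IMMSYN11_09	IMMSYN11_10	IMMSYN11_11	IMMSYN11_12	IMMSYN11_13	IMMSYN11_14	IMMSYN11_15
Gamma delta T cell	SYNTHETIC placeholder genes for testing only	IMMSYN12_01	IMMSYN12_02	IMMSYN12_03	IMMSYN12_04	IMMSYN12_05	IMMSYN12_06	IMMSYN12_07	IMMSYN12_08	IMMSYN12_09	IMMSYN12_10	IMMSYN12_11	IMMSYN12_12	IMMSYN12_13	IMMSYN12_14	IMMSYN12_15
Immature B cell	SYNTHETIC placeholder genes for testing only	IMMSYN13_01	IMMSYN13_02	IMMSYN13_03	IMMSYN13_04	IMMSYN13_05	IMMSYN13_06	IMMSYN13_07	IMMSYN13_08	IMMSYN13_09	IMMSYN13_10	IMMSYN13_11	IMMSYN13_12	IMMSYN13_13	IMMSYN13_14	IMMSYN13_15
Immature dendritic cell	SYNTHETIC placeholder genes for testing only	IMMSYN14_01	IMMSYN14_02	IMMSYN14_03	IMMSYN14_04	IMMSYN14_05	IMMSYN14_06	IMMSYN14_07	IMMSYN14_08	IMMSYN14_09	IMMSYN14_10	IMMSYN14_11	IMMSYN14_12	IMMSYN14_13	IMMSYN14_14	IMMSYN14_15
MDSC	SYNTHETIC placeholder genes for testing only	IMMSYN15_01	IMMSYN15_02	IMMSYN15_03	IMMSYN15_04	IMMSYN15_05	IMMSYN15_06	IMMSYN15_07	IMMSYN15_08	IMMSYN15_09	IMMSYN15_10	IMMSYN15_11	IMMSYN15_12	IMMSYN15_13	IMMSYN15_14	IMMSYN15_15
Macrophage	SYNTHETIC placeholder genes for testing only	IMMSYN16_01	IMMSYN16_02	IMMSYN16_03	IMMSYN16_04	IMMSYN16_05	IMMSYN16_06	IMMSYN16_07	IMMSYN16_08	IMMSYN16_09	IMMSYN16_10	IMMSYN16_11	IMMSYN16_12	IMMSYN16_13	IMMSYN16_14	IMMSYN16_15
Mast cell	SYNTHETIC placeholder genes for testing only	IMMSYN17_01	IMMSYN17_02	IMMSYN17_03	IMMSYN17_04	IMMSYN17_05	IMMSYN17_06	IMMSYN17_07	IMMSYN17_08	IMMSYN17_09	IMMSYN17_10	IMMSYN17_11	IMMSYN17_12	IMMSYN17_13	IMMSYN17_14	IMMSYN17_15
Memory B cell	SYNTHETIC placeholder genes for testing only	IMMSYN18_01	IMMSYN18_02	IMMSYN18_03	IMMSYN18_04	IMMSYN18_05	IMMSYN18_06	IMMSYN18_07	IMMSYN18_08	IMMSYN18_09	IMMSYN18_10	IMMSYN18_11	IMMSYN18_12	IMMSYN18_13	IMMSYN18_14	IMMSYN18_15
Monocyte	SYNTHETIC placeholder genes for testing only	IMMSYN19_01	IMMSYN19_02	IMMSYN19_03	IMMSYN19_04	IMMSYN19_05	IMMSYN19_06	IMMSYN19_07	IMMSYN19_08	IMMSYN19_09	IMMSYN19_10	IMMSYN19_11	IMMSYN19_12	IMMSYN19_13	IMMSYN19_14	IMMSYN19_15
Natural killer T cell	SYNTHETIC placeholder genes for testing only	IMMSYN20_01	IMMSYN20_02	IMMSYN20_03	IMMSYN20_04	IMMSYN20_05	IMMSYN20_06	IMMSYN20_07	IMMSYN20_08	IMMSYN20_09	IMMSYN20_10	IMMSYN20_11	IMMSYN20_12	IMMSYN20_13	IMMSYN20_14	IMMSYN20_15
Natural killer cell	SYNTHETIC placeholder genes for testing only	IMMSYN21_01	IMMSYN21_02	IMMSYN21_03	IMMSYN21_04	IMMSYN21_05	IMMSYN21_06	IMMSYN21_07	IMMSYN21_08	IMMSYN21_09	IMMSYN21_10	IMMSYN21_11	IMMSYN21_12	IMMSYN21_13	IMMSYN21_14	IMMSYN21_15
Neutrophil	SYNTHETIC placeholder genes for testing only	IMMSYN22_01	IMMSYN22_02	IMMSYN22_03	IMMSYN22_04	IMMSYN22_05	IMMSYN22_06	IMMSYN22_07	IMMSYN22_08	IMMSYN22_09	IMMSYN22_10	IMMSYN22_11	IMMSYN22_12	IMMSYN22_13	IMMSYN22_14	IMMSYN22_15
Plasmacytoid dendritic cell	SYNTHETIC placeholder genes for testing only	IMMSYN23_01	IMMSYN23_02	IMMSYN23_03	IMMSYN23_04	IMMSYN23_05	IMMSYN23_06	IMMSYN23_07	IMMSYN23_08	IMMSYN23_09	IMMSYN23_10	IMMSYN23_11	IMMSYN23_12	IMMSYN23_13	IMMSYN23_14	IMMSYN23_15
Regulatory T cell	SYNTHETIC placeholder genes for testing only	IMMSYN24_01	IMMSYN24_02	IMMSYN24_03	IMMSYN24_04	IMMSYN24_05	IMMSYN24_06	IMMSYN24_07	IMMSYN24_08	IMMSYN24_09	IMMSYN24_10	IMMSYN24_11	IMMSYN24_12	IMMSYN24_13	IMMSYN24_14	IMMSYN24_15
T follicular helper cell	SYNTHETIC placeholder genes for testing only	IMMSYN25_01	IMMSYN25_02	IMMSYN25_03	IMMSYN25_04	IMMSYN25_05	IMMSYN25_06	IMMSYN25_07	IMMSYN25_08	IMMSYN25_09	IMMSYN25_10	IMMSYN25_11	IMMSYN25_12	IMMSYN25_13	IMMSYN25_14	IMMSYN25_15
Type 1 T helper cell	SYNTHETIC placeholder genes for testing only	IMMSYN26_01	IMMSYN26_02	IMMSYN26_03	IMMSYN26_04	IMMSYN26_05	IMMSYN26_06	IMMSYN26_07	IMMSYN26_08	IMMSYN26_09	IMMSYN26_10	IMMSYN26_11	IMMSYN26_12	IMMSYN26_13	IMMSYN26_14	IMMSYN26_15
Type 17 T helper cell	SYNTHETIC placeholder genes for testing only	IMMSYN27_01	IMMSYN27_02	IMMSYN27_03	IMMSYN27_04	IMMSYN27_05	IMMSYN27_06	IMMSYN27_07	IMMSYN27_08	IMMSYN27_09	IMMSYN27_10	IMMSYN27_11	IMMSYN27_12	IMMSYN27_13	IMMSYN27_14	IMMSYN27_15
Type 2 T helper cell	SYNTHETIC placeholder genes for testing only	IMMSYN28_01	IMMSYN28_02	IMMSYN28_03	IMMSYN28_04	IMMSYN28_05	IMMSYN28_06	IMMSYN28_07	IMMSYN28_08	IMMSYN28_09	IMMSYN28_10	IMMSYN28_11	IMMSYN28_12	IMMSYN28_13	IMMSYN28_14	IMMSYN28_15
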
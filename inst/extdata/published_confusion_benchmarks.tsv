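feature_set	magnification	classifier	TP	FN	TN	FP	AC	MC	PR	SE	SP	FS	known_typo
DF-softmax-bench	100x	VGG16	142	11	143	4	95.0000	5.0000	97.2603	92.8105	97.2789	94.9833
DF-softmax-bench	100x	VGG19	146	8	138	8	94.6667	5.3333	94.8052	94.8052	94.5205	94.8052
DF-softmax-bench	100x	ResNet18	134	19	146	1	93.3333	6.6667	99.2593	87.5817	99.3197	93.0556
DF-softmax-bench	100x	ResNet50	135	18	147	0	94.0000	6.0000	100	88.2353	100	93.7500
DF-softmax-bench	100x	ResNet101	141	12	143	4	94.6667	5.3333	97.2414	92.1569	97.2789	94.6309
DF-softmax-bench	100x	DenseNet201	144	9	143	4	95.6667	4.3333	97.2973	94.1176	97.2789	95.6811
DF-softmax-bench	400x	VGG16	141	7	144	8	95.0000	5.0000	94.6309	95.2703	94.7368	94.9495
DF-softmax-bench	400x	VGG19	139	10	142	9	93.6667	6.3333	93.9189	93.2886	94.0397	93.6027
DF-softmax-bench	400x	ResNet18	140	8	138	14	92.6667	7.3333	90.9091	94.5946	90.7895	92.7152
DF-softmax-bench	400x	ResNet50	139	13	141	7	93.3333	6.6667	95.2055	91.4474	95.2703	93.2886
DF-softmax-bench	400x	ResNet101	141	7	142	10	94.3333	5.6667	93.3775	95.2703	93.4211	94.3144
DF-softmax-bench	400x	DenseNet201	143	5	143	9	95.3333	4.6667	94.0789	96.6216	94.0789	95.3333
VGG16	100x	SoftMax	142	11	143	4	95.0000	5.0000	97.2603	92.8105	97.2789	94.9833
VGG16	100x	DT	142	6	142	10	94.6667	5.3333	93.4211	95.9459	93.4211	94.6667
VGG16	100x	RF	144	7	138	11	94.0000	6.0000	92.9032	95.3642	92.6174	94.1176
VGG16	100x	KNN	140	9	144	7	94.6667	5.3333	95.2381	93.9597	95.3642	94.5946
VGG16	100x	SVM	141	10	143	6	94.6667	5.3333	95.9184	93.3775	95.9732	94.6309
VGG16	400x	SoftMax	141	7	144	8	95.0000	5.0000	94.6309	95.2703	94.7368	94.9495
VGG16	400x	DT	142	10	143	5	95.0000	5.0000	96.5986	93.4211	96.6216	94.9833
VGG16	400x	RF	141	7	142	10	94.3333	5.6667	93.3775	95.2703	93.4211	94.3144
VGG16	400x	KNN	143	5	143	9	95.3333	4.6667	94.0789	96.6216	94.0789	95.3333
VGG16	400x	SVM	142	9	143	6	95.0000	5.0000	95.9459	94.0397	95.9732	94.9833
DenseNet201	100x	SoftMax	144	9	143	4	95.6667	4.3333	97.2973	94.1176	97.2789	95.6811
DenseNet201	100x	DT	143	8	140	9	94.3333	5.6667	94.0789	94.7020	93.9597	94.3894
DenseNet201	100x	RF	142	9	144	5	95.3333	4.6667	96.5986	94.0397	96.6443	95.3020
DenseNet201	100x	KNN	144	8	144	4	96.0000	4.0000	97.2973	94.7368	97.2973	96.0000
DenseNet201	100x	SVM	143	4	143	10	95.3333	4.6667	93.4641	97.2789	93.4641	95.3333
DenseNet201	400x	SoftMax	143	5	143	9	95.3333	4.6667	94.0789	96.6216	94.0789	95.3333
DenseNet201	400x	DT	141	8	143	8	94.6667	5.3333	94.6309	94.6309	94.7020	94.6309
DenseNet201	400x	RF	142	10	143	5	95.0000	5.0000	96.5986	93.4211	96.6216	94.9833
DenseNet201	400x	KNN	144	3	143	10	95.6667	4.3333	93.5065	97.9592	93.4641	95.6811
DenseNet201	400x	SVM	144	5	142	9	95.3333	4.6667	94.1176	96.6443	94.0397	95.3642
DDF	100x	SoftMax	146	3	146	5	97.3333	2.6667	96.6887	97.9866	96.6887	97.3333
DDF	100x	DT	146	6	145	3	97.0000	3.0000	97.9866	96.0526	97.9730	97.0100
DDF	100x	RF	147	4	144	5	97.0000	3.0000	96.7105	97.3510	96.6443	97.0297
DDF	100x	KNN	147	2	146	5	97.6667	2.3333	96.7105	98.6577	96.6887	97.6744
DDF	100x	SVM	143	6	147	4	96.6667	3.3333	97.2789	95.9732	97.3510	96.6216
DDF	400x	SoftMax	145	3	146	6	97.0000	3.0000	96.0265	97.9730	96.0526	96.9900
DDF	400x	DT	145	6	147	2	97.3333	2.6667	98.6395	96.0265	98.6577	97.3154
DDF	400x	RF	146	3	143	8	96.3333	3.6667	94.8052	97.9866	94.7020	96.3696
DDF	400x	KNN	146	7	146	1	97.3333	2.6667	99.3197	95.4248	99.3197	97.3333
DDF	400x	SVM	146	5	144	5	96.6667	3.3333	96.6887	96.6887	96.6443	96.6887
EDF	100x	SoftMax	145	4	144	7	96.3333	3.6667	95.3947	97.3154	95.3642	96.3455
EDF	100x	DT	145	6	145	4	96.6667	3.3333	97.3154	96.0265	97.3154	96.6667
EDF	100x	RF	146	3	143	8	96.3333	3.6667	94.8052	97.9866	94.7020	96.3696
EDF	100x	KNN	145	6	146	3	97.0000	3.0000	97.9730	96.0265	97.9866	96.9900
EDF	100x	SVM	145	4	145	6	96.6667	3.3333	96.0265	97.3154	96.0265	96.6667
EDF	400x	SoftMax	146	4	143	7	96.3333	3.6667	95.4248	97.3333	95.3333	96.3696
EDF	400x	DT	145	4	144	7	96.3333	3.6667	95.3947	97.3154	95.3642	96.3455
EDF	400x	RF	144	7	146	3	96.6667	3.3333	97.9592	95.3642	97.9866	96.6443
EDF	400x	KNN	145	6	145	4	96.6667	3.3333	97.3154	96.0265	97.3154	96.6667
EDF	400x	SVM	143	6	146	5	96.3333	3.6667	96.6216	95.9732	96.6887	96.2963
DDF+HF	100x	SoftMax	147	2	149	2	98.6667	1.3333	98.6577	98.6577	98.6755	98.6577
DDF+HF	100x	DT	148	0	149	3	99.0000	1.0000	98.0132	100	98.0263	98.9967
DDF+HF	100x	RF	149	2	149	0	99.3333	0.6667	100	98.6755	100	99.3333
DDF+HF	100x	KNN	151	0	149	0	100	0.0000	100	100	100	100
DDF+HF	100x	SVM	150	1	149	0	99.6667	0.3333	100	99.3377	100	99.6678
DDF+HF	400x	SoftMax	148	1	149	2	99.0000	1.0000	98.6667	99.3289	98.6755	98.9967
DDF+HF	400x	DT	150	2	148	0	99.3333	0.6667	100	98.6842	100	99.3377
DDF+HF	400x	RF	149	0	150	1	99.6667	0.3333	99.3333	100	99.3377	99.6656
DDF+HF	400x	KNN	150	0	150	0	100	1.0000	100	100	100	100	MC
DDF+HF	400x	SVM	148	1	151	0	99.6667	0.3333	100	99.3289	100	99.6633
EDF+HF	100x	SoftMax	149	0	149	2	99.3333	0.6667	98.6755	100	98.6755	99.3333
EDF+HF	100x	DT	148	2	149	1	99.0000	1.0000	99.3289	98.6667	99.3333	98.9967
EDF+HF	100x	RF	150	1	147	2	99.0000	1.0000	98.6842	99.3377	98.6577	99.0099
EDF+HF	100x	KNN	149	2	149	0	99.3333	0.6667	100	98.6755	100	99.3333
EDF+HF	100x	SVM	149	0	148	3	99.0000	1.0000	98.0263	100	98.0132	99.0033
EDF+HF	400x	SoftMax	149	1	148	2	99.0000	1.0000	98.6755	99.3333	98.6667	99.0033
EDF+HF	400x	DT	148	1	149	2	99.0000	1.0000	98.6667	99.3289	98.6755	98.9967
EDF+HF	400x	RF	149	2	149	0	99.3333	0.6667	100	98.6755	100	99.3333
EDF+HF	400x	KNN	150	1	148	1	99.3333	0.6667	99.3377	99.3377	99.3289	99.3377
EDF+HF	400x	SVM	149	0	148	3	99.0000	1.0000	98.0263	100	98.0132	99.0033
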
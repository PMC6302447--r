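oligo	T1	T2	T3	T4	T5	T6	T7	T8	T9	T10	T11	T12
AAA	-0.681	0.798	-0.396	0.484	-0.553	0.927	0.832	-1.052	0.148	-0.728	-0.948	0.871
AAC	-0.745	-0.479	0.935	0.674	0.162	0.762	1.452	0.301	0.465	-0.945	0.111	0.434
AAG	0.34	-0.098	1.927	-0.163	-0.534	-1.064	-0.931	0.411	-0.521	0.046	-0.501	1.315
AAT	0.017	-1.505	1.2	0.788	-0.251	1.45	-1.065	0.507	0.624	-0.615	0.975	-0.539
ACA	0.062	-0.538	-0.112	-0.042	-1.278	-0.185	1.362	-0.289	1.664	-1.071	-0.568	-0.133
ACC	0.908	1.067	0.286	-0.365	-1.991	-1.659	1.833	0.294	0.674	-1.121	0.539	-1.453
ACG	0.611	1.493	1.945	-0.322	-0.734	0.966	0.831	0.35	-0.467	1.067	-0.664	2.019
ACT	-1.39	0.728	0.825	1.341	0.901	-1.956	1.519	-0.825	-0.04	0.96	-0.407	0.745
AGA	-0.09	0.269	0.552	0.486	-1.365	-1.466	0.737	0.236	-0.274	-0.744	0.342	1.255
AGC	-0.223	0.505	-0.374	0.963	0.714	0.407	0.067	-0.572	-0.866	-0.835	2.089	-1.043
AGG	-0.052	-1.05	0.498	-0.633	0.843	1.455	0.008	0.733	-0.417	-0.088	-0.471	0.04
AGT	1.206	0.552	0.621	-0.66	0.126	1.048	0.79	-0.752	-0.275	0.367	-0.484	-0.393
ATA	-0.551	-0.114	-0.429	1.267	-1.264	1.246	2.052	-0.262	-0.287	0.389	-1.386	1.268
ATC	0.219	-1.212	-0.95	-0.711	0.985	0.132	0.001	1.64	-1.134	0.634	0.757	-1.306
ATG	-0.968	1.461	0.67	0.442	-0.127	-1.863	-1.188	0.78	-2.075	-0.883	-0.465	0.361
ATT	-0.891	0.268	-0.398	0.171	-1.492	-0.586	-1.339	1.03	0.177	-0.855	0.065	0.106
CAA	1.16	0.312	-0.043	-1.431	-0.921	0.417	0.536	-1.706	0.661	1.383	0.535	1.826
CAC	-0.896	0.411	0.516	0.978	0.075	-0.414	-0.797	0.303	-1.555	0.132	-0.007	0.6
CAG	-1.323	0.526	-1.9	-2.899	0.9	-1.581	-0.031	-0.537	2.274	0.293	-0.482	1.571
CAT	-1.254	-1.031	-0.358	-1.586	-0.727	0.831	0.107	-0.317	-2.224	1.434	-0.035	1.22
CCA	2.14	0.114	0.268	-0.709	-0.322	0.262	0.703	-1.237	-1.698	-0.837	0.57	-1.814
CCC	-1.478	-0.052	0.576	0.742	-1.2	-0.172	0.206	-2.305	0.83	0.442	0.143	-0.24
CCG	-0.243	-1.452	-0.711	0.764	-2.289	1.187	0.653	-0.1	-2.272	-0.611	-0.547	0.931
CCT	-0.559	0.785	-0.957	0.544	-1.532	-1.636	0.865	0.424	0.998	-0.206	-0.208	-1.578
CGA	-0.796	-0.057	0.867	-1.119	-1.78	-1.407	0.672	-0.788	-0.466	-0.222	1.488	1.484
CGC	0.478	1.383	-0.732	0.303	-1.249	-0.473	-0.446	-0.493	-0.443	1.627	0.337	-1.03
CGG	-0.515	-0.638	-0.688	0.183	-1.663	0.683	0.338	-1.161	0.353	1.434	0.897	0.726
CGT	0.816	-0.047	1.485	0.613	0.712	0.327	1.156	1.553	-0.067	0.333	-1.165	0.008
CTA	1.516	0.119	-0.062	-0.588	-0.054	1.94	-0.142	1.61	0.3	-1.964	2.43	-0.063
CTC	0.843	0.635	0.892	0.699	0.304	1.289	-0.547	-0.906	0.587	-0.219	0.35	0.032
CTG	-0.989	0.143	-1.108	-0.865	0.296	-0.189	-1.877	0.086	-1.362	-0.609	0.095	-0.656
CTT	-1.406	0.722	1.606	-0.064	-0.762	0.53	0.238	-1.376	1.574	-0.975	1.087	-0.15
GAA	-1.31	-0.344	-0.204	1.797	-0.891	-1.515	0.838	-0.878	0.202	-0.623	-0.351	-1.662
GAC	-0.025	-0.084	0.028	-1.717	-0.379	0.584	0.072	0.995	0.592	1.17	0.85	0.435
GAG	0.569	1.109	-0.626	0.564	1.774	-0.037	-0.262	-1.854	0.017	0.129	-0.064	-0.633
GAT	2.919	0.13	-2.84	-1.991	0.106	0.521	-1.152	0.768	-0.171	-2.045	-0.306	-0.316
GCA	1.392	-0.709	0.147	0.104	-1.256	-0.953	0.437	-0.207	-1.339	-1.168	-0.533	-1.434
GCC	-0.658	-0.289	-0.787	-0.187	-0.457	2.189	0.961	0.445	1.564	0.178	0.112	0.162
GCG	0.236	1.296	-0.805	-0.359	-0.945	-0.973	-0.272	-0.449	-0.066	-2.11	1.297	-0.48
GCT	2.7	-1.275	0.66	-0.768	-0.789	1.885	0.56	-2.172	-1.058	-0.391	-1.797	3.074
GGA	0.713	0.529	0.523	0.195	-0.902	0.685	-0.044	0.611	0.304	-1.446	-0.129	0.46
GGC	0.098	-0.639	-0.56	-1.6	0.065	1.667	0.007	-1.146	0.302	0.547	0.429	-0.169
GGG	-0.713	1.369	-0.36	-0.173	0.095	-0.724	-0.396	-2.09	1.453	-1.752	-0.684	0.361
GGT	0.096	-0.003	-0.176	-0.934	0.149	1.033	-0.797	0.17	-0.273	0.771	1.341	-0.33
GTA	-0.298	0.342	-0.6	1.04	2.368	-0.918	-0.408	2.092	1.026	1.472	-0.398	1.028
GTC	0.906	1.092	-0.598	-0.923	0.098	-0.753	0.866	1.234	-1.177	-0.851	-1.824	0.516
GTG	-1.702	-1.154	0.101	-1.856	-0.862	-0.488	-0.764	0.576	-0.593	-0.272	0.12	0.938
GTT	1.262	-0.264	-1.464	0.825	0.32	-1.597	-0.748	1.109	1.228	-0.555	-0.239	-1.141
TAA	0.774	0.715	-0.603	0.514	0.632	-1.481	1.407	-0.628	-1.51	0.366	-0.74	1.34
TAC	0.829	0.781	0.26	0.582	1.38	-1.54	-0.352	-1.794	0.388	1.7	0.211	1.729
TAG	0.861	1.035	-0.405	-0.658	1.44	0.464	-0.504	-0.507	-0.674	-1.399	0.925	0.384
TAT	-0.498	-0.098	-0.502	-0.837	-0.714	0.252	-0.172	0.002	0.735	0.604	-0.278	0.078
TCA	0.399	-1.389	-0.151	0.591	-0.799	0.899	0.91	0.121	0.794	1.801	-0.528	-0.779
TCC	-1.923	0.557	-0.381	0.929	-0.218	0.769	0.541	0.982	1.591	-0.467	-0.141	0.987
TCG	-0.873	0.571	-0.2	0.367	-1.103	0.686	0.911	0.081	-0.19	-1.645	0.052	0.14
TCT	-0.205	0.798	-0.503	0.915	0.277	0.064	-0.361	-0.148	-0.663	0.208	-0.833	-1.412
TGA	0.875	1.437	-0.923	-1.739	-1.437	-0.171	-0.445	0.242	0.402	-0.597	-0.712	-0.856
TGC	-1.06	-0.374	-0.028	-1.052	-0.294	-0.969	1.051	0.738	-0.622	1.341	-0.177	0.842
TGG	-0.583	1.382	0.772	-0.256	-0.993	0.662	0.72	1.08	1.573	0.635	0.334	0.085
TGT	-0.057	-2.77	-0.043	0.334	0.847	0.113	-0.276	-1.855	0.884	-0.56	-0.497	0.144
TTA	0.74	-0.19	-0.31	0.1	1.411	-0.512	-0.06	-1.731	0.448	-0.27	0.293	1.043
TTC	0.549	0.447	-0.883	1.27	0.522	1.349	-1.818	-1.171	-0.176	-0.128	-0.691	1.521
TTG	-0.517	-0.601	0.022	-1.024	-1.32	-0.895	1.482	0.068	0.09	0.139	-1.177	0.224
TTT	-0.609	-0.533	-0.44	-0.208	0.999	1.126	-0.855	-1.115	0.843	0.487	-0.013	0.764
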
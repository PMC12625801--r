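(((((((((((Alouatta_seniculus:12.8816025869735,Aotus_trivirgatus:12.8816025869735):4.20712021805056,(Archaeoindris_fontoynontii:1.29151895866276,Archaeolemur_edwardsi:1.29151895866276):15.7972038463613):2.35731290194479,((Archaeolemur_majori:3.65587058373827,Arctocebus_calabarensis:3.65587058373827):9.51101117947651,Ateles_geoffroyi:13.1668817632148):6.27915394375412):1.91548567288424,(Avahi_laniger:2.2412448630667,Babakotia_radofilai:2.2412448630667):19.1202765167864):0.547561609783815,(Brachyteles_arachnoides:2.78518711914686,Cacajao_calvus:2.78518711914686):19.1238958704901):0.285042019199186,((Callicebus_moloch:8.65960181889414,Callimico_goeldii:8.65960181889414):12.8538533657448,Callithrix_jacchus:21.5134551846389):0.680669824197239):8.30824306463283,(((((Cebuella_pygmaea:5.11260388438119,Cebus_apella:5.11260388438119):2.9024003654568,Cercocebus_atys:8.01500424983799):6.8586164662274,Cercopithecus_mitis:14.8736207160654):6.22111743952966,Cheirogaleus_medius:21.094738155595):7.10362125071886,(((Chiropotes_satanas:2.98710862978371,Chlorocebus_aethiops:2.98710862978371):9.81411387724059,Colobus_guereza:12.8012225070243):12.1862923627467,Daubentonia_madagascariensis:24.987514869771):3.21084453654296):2.30400866715506):8.08516111141019,(((((Daubentonia_robusta:0.874907471427562,Erythrocebus_patas:0.874907471427562):7.14419796347579,Eulemur_fulvus:8.01910543490335):13.7539839922923,((Eulemur_macaco:4.95392773835339,Euoticus_elegantulus:4.95392773835339):15.4158229513025,Galago_senegalensis:20.3697506896559):1.40333873753976):0.235803416386204,((Galagoides_demidoff:1.97827341480803,Gorilla_gorilla:1.97827341480803):9.99360087818567,Hapalemur_griseus:11.9718742929937):10.0370185505882):6.44402126657276,((Homo_sapiens:3.9517008130725,Hylobates_lar:3.9517008130725):13.0469673064497,(Indri_indri:2.73162268812228,Lagothrix_lagotricha:2.73162268812228):14.2670454313999):11.4542459906325):10.1346150747245):3.84142901394511,((((((Lemur_catta:1.8693292208879,Leontopithecus_rosalia:1.8693292208879):15.3785461607812,Lepilemur_mustelinus:17.2478753816691):4.62168782985945,((Loris_tardigradus:0.173681516758207,Macaca_fascicularis:0.173681516758207):5.49853916400743,Macaca_mulatta:5.67222068076564):16.1973425307629):1.48693795041319,(Mandrillus_sphinx:21.036221199914,Megaladapis_edwardsi:21.036221199914):2.32027996202769):8.22546655496324,((((Megaladapis_grandidieri:5.7745387322381,Megaladapis_madagascariensis:5.7745387322381):8.59648995423432,Mesopropithecus_dolichobrachion:14.3710286864724):4.47403654067916,Mesopropithecus_globiceps:18.8450652271516):7.56973697079251,(Mesopropithecus_pithecoides:9.67592216446358,Microcebus_murinus:9.67592216446358):16.7388800334805):5.16716551896087):2.05511936165666,(Mirza_coquereli:2.95918533388723,Nasalis_larvatus:2.95918533388723):30.6779017446744):8.79187112026263):1.90339777648104,((((((Nycticebus_coucang:7.49955998364971,Otolemur_crassicaudatus:7.49955998364971):7.94933918253894,Pachylemur_insignis:15.4488991661886):0.020362230791751,(Pachylemur_jullyi:7.53825423167693,Paleopropithecus_ingens:7.53825423167693):7.93100716530347):9.98111503830936,Paleopropithecus_maximus:25.4503764352898):0.690487307038771,((Pan_paniscus:2.88218128613688,Pan_troglodytes:2.88218128613688):15.5711011681549,Papio_anubis:18.4532824542917):7.68758128803679):1.08919792262231,((((Perodicticus_potto:7.77340457880844,Piliocolobus_badius:7.77340457880844):5.90631354810075,Pithecia_pithecia:13.6797181269092):5.75126758323869,Pongo_pygmaeus:19.4309857101479):0.318826897908333,(Presbytis_melalophos:2.40216947939517,Propithecus_diadema:2.40216947939517):17.347643128661):7.48024905689463):17.1022943103545):15.6676440246947,((((Propithecus_tattersalli:8.65635059066461,Propithecus_verreauxi:8.65635059066461):10.9916000864037,Saguinus_oedipus:19.6479506770683):3.05262284875637,((Saimiri_sciureus:0.395927976902175,Semnopithecus_entellus:0.395927976902175):1.94409165801307,Symphalangus_syndactylus:2.34001963491523):20.3605538909094):2.07154575370606,(((Tarsius_syrichta:5.84405296596698,Theropithecus_gelada:5.84405296596698):3.87861224122849,Trachypithecus_cristatus:9.72266520719547):3.42374812484289,Varecia_variegata:13.1464133320384):11.6257059474923):35.2278807204693);
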
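"frame","x1","x2","x3","x4","x5","x6","x7","x8","x9","x10","x11","x12","x13","x14","x15","x16","x17","x18","x19","x20","x21","x22","x23","x24","x25","x26","x27","x28","x29","x30","x31","x32","x33","x34","x35","x36","x37","x38","x39","x40","x41","x42","x43","x44","x45","x46","x47","x48","x49","x50","x51","x52","x53","x54","x55","x56","x57","x58","x59","x60","x61","x62","x63","x64","x65","x66","x67","x68","y1","y2","y3","y4","y5","y6","y7","y8","y9","y10","y11","y12","y13","y14","y15","y16","y17","y18","y19","y20","y21","y22","y23","y24","y25","y26","y27","y28","y29","y30","y31","y32","y33","y34","y35","y36","y37","y38","y39","y40","y41","y42","y43","y44","y45","y46","y47","y48","y49","y50","y51","y52","y53","y54","y55","y56","y57","y58","y59","y60","y61","y62","y63","y64","y65","y66","y67","y68"
1,25.57,27.93,30.62,32.15,35.67,40.99,46.17,52.81,60.53,65.69,72.26,76.24,80.34,87.23,88.91,91.17,93.54,31.46,35.47,41.92,45.02,51.43,70.27,72.32,77.35,80.49,84.85,59.8,59.67,59.33,58.9,50.52,52.33,58.68,62.56,66.36,47.69,44.53,37.79,32.5,37.61,44.15,82.32,80.34,73.51,70.16,73.26,81.39,71.03,70.3,65.66,58.83,51.74,47.05,42.98,45.42,53.32,59.12,66.57,69.64,70.08,65.24,58.24,50.04,49.76,54.6,57.77,65.26,51.02,60.36,69.66,76,79.76,84.13,90.18,91.76,92.19,91.88,88,84.83,81.31,75.71,67.08,59.47,53.87,31.9,31.75,30.29,32.63,33.45,34.5,34.28,30.91,32.98,32.94,40.06,45.79,51.07,57.15,61.35,62.2,62.11,63.13,58.91,41.23,39.29,39.52,41.09,43.63,43.52,41.85,38.67,37.66,40.84,44.67,42.45,76.32,70.99,67.99,68.66,66.38,70.83,75.53,78.4,82.23,82.6,80.34,77.83,74.37,73.16,70.98,71.25,75.6,77.66,78,75.3
2,25.83,28.65,26.94,28.61,34.76,39.97,44.04,53.24,60.6,64.23,68.87,73.79,81.37,85.36,89.28,91.38,91.85,30.24,36,38.76,44.63,50.49,65.3,71.95,76.57,82.41,86.32,58.78,60.06,61.14,57.14,51.09,54.38,59.52,62.7,64.55,47.66,42.48,35.5,32.05,34.34,43.5,82.49,80.47,73.06,70.31,75.78,79.7,72.26,70.4,66.36,57.36,50.76,44.9,44.81,45.47,50.93,57.87,68.08,71.52,66.62,64.95,58.94,51.42,47.74,53.27,58.73,63.63,47.82,56.56,66.29,72.73,78.24,83.05,86.51,88.16,90.52,89.32,86.13,82.93,77.82,69.69,63.19,59.32,50.02,29.14,28.59,27.23,28.08,28.43,32.48,29.03,28.9,27.88,30.66,37.68,42.19,48.67,53.83,56.96,58.83,57.52,57.12,54.67,39.3,38.92,36.41,38.56,38.84,40.29,37.24,36.08,35.22,39.09,42.21,39.34,73.08,67.67,65.54,63.79,63.44,69.26,72.07,74.74,79.7,79.44,78.79,73.56,71.8,68.8,68.92,68.08,72.01,73.7,72.64,74.74
3,21.3,24.53,24.87,30.49,33.61,37.16,44.26,52.44,58.18,62.77,68.03,74.13,80.4,82.77,85.86,87.93,88.67,29.52,34.22,39.06,44.68,47.16,66.87,69.54,76.12,77.98,84.2,57.45,56.52,56.25,56.37,48.75,52.46,54.79,59.99,64.18,43.62,42.24,34.36,31.57,36.86,41.97,81.77,77.59,68.51,67.69,71.48,79.14,70.52,69.54,65.15,57.71,48.4,43.27,42.97,42.21,49.67,56.64,65.53,70.18,65.39,62.81,55.07,49.51,46.18,50.98,56.53,63.33,48.41,57.25,66.1,70.94,78.81,83.7,86.3,90.79,88.37,89.07,86.98,83.17,77.47,72.26,65.94,57.77,49.83,30.46,27.42,29.39,29.77,31.02,31.95,30.95,28.84,28.11,31.07,37.97,44.64,50.31,54.82,56.72,59.67,59.58,58.71,57.99,39.37,34.94,35.85,37.78,41.18,40.62,37.89,36.59,35.68,37.83,42.1,40.14,72.86,69.89,67.37,64.98,66.35,68.86,73.76,77.21,77.92,81.29,79.85,75.72,72.43,68.92,69.59,68.74,72.98,76.45,74.98,73.94
4,23.77,25.96,26.33,30.49,33.41,40.55,43.15,52.4,56.77,63.3,69.25,76.8,82.3,85.07,88.92,90.03,91.48,29.95,35.99,40.48,44.07,48.23,67.51,70.6,75.7,80.42,86.61,58.09,56.65,58.42,59.17,49.51,53.74,58.31,61.72,65.03,46.91,42.32,37.56,32.45,35.76,43.87,85.59,80.03,70.63,71.43,72.83,76.58,69.83,70.13,66.65,57.39,49.35,44.86,44.73,44.47,50.42,59.26,66.7,70.34,65.8,64.46,56.36,52.51,46.22,53.84,56.81,64.06,50.28,55.95,65.08,71.99,78.43,83.11,87.23,89.57,88.56,88.16,87.04,82.72,78.47,71.36,64.93,59.18,50.14,31.38,27.86,29.35,29.7,30.65,30.85,29.01,27.67,29.52,31.32,38.34,44.35,48.39,54.62,57.14,58.67,59.11,59.82,58.86,39.87,37.19,35.72,38.78,39.61,41.6,38.69,36.48,37.14,39.16,40.71,40.45,72.93,68.29,65.55,65.21,64.37,70.6,72.5,77.03,79.98,79.56,75.67,75.79,69.7,67.77,69.54,69.27,72.18,75.37,74.39,74.74
5,23.63,26.65,26.86,28.4,33.73,40.94,42.48,49.61,57.15,64.81,69.22,75.42,80.28,84.92,87.8,88.48,92.2,29.37,34.53,39.41,46.9,48.55,68.36,70.48,75.85,78.95,84.41,55.32,56.32,55.92,57.28,49.14,53.03,55.99,63.46,64.39,46.25,41.56,34.85,31.42,36.41,42.08,81.4,79.12,71.89,70.28,72.35,79.42,70.32,71.07,65.03,59.13,50.45,42.19,42.91,44.37,50.3,56.95,66.59,70.66,66.42,62.74,57.23,52.14,49.82,52.98,57.92,64.02,50.66,56.83,67.49,73.91,80.26,83.16,89.65,92.27,89.45,89.42,89.62,85.89,79.15,71.57,63.99,59.83,51.11,31.59,28.5,29.66,31.1,32.33,31.97,32.29,30.68,31.88,32.76,39.72,46.44,50.3,53,59.38,59.71,60.37,61.68,56.63,41.27,36.71,40.32,38.24,40.76,42.51,39.8,35.96,36.6,40.09,41.61,42.28,73.51,68.52,64.84,61.9,62.89,66.23,72.34,74.3,78.12,78.81,79.33,74.53,71.18,68.78,68.69,68.16,71.26,75.6,73.15,72.87
6,22.86,22.83,24.97,24.97,30.34,38.18,41.01,47.12,54.84,62.38,67.7,74.78,78.2,81.4,84.98,88.33,88.24,28.12,33.43,36.23,43.68,46.05,64.06,66.69,76.06,78.38,85.47,54.52,54.44,55.93,54.21,47.31,49.34,55.57,60.21,63.09,43.4,40.65,33.56,31.09,32.94,40.11,80.7,76.66,68.43,65.83,70.49,76.94,68.26,66.38,63.81,56.19,47.04,42.02,41.15,40.16,50.36,54.71,64.97,67.79,63.72,61.56,53.4,48.19,46.37,50.19,54.29,60.91,49.29,58.75,67.12,74.74,78.88,84.36,85.51,91.51,90.33,89.99,87.9,85.07,82.22,72.37,66.35,58.33,52.45,31.97,28.25,30.66,31.76,31.1,31.1,32.01,28.99,30.96,32.32,37.82,45,50.42,54.31,59.82,59.21,60.22,60.63,59.05,38.61,37.13,36.95,38.03,41.92,41.33,39.53,38.78,36.97,39.97,40.52,43.56,72.64,68.71,66.27,64.82,64.25,69.99,74.15,78.26,79.53,81.45,79.67,76.09,73.29,70.66,70.9,69.41,72.53,74.78,76.53,75.18
7,21.17,22.28,23.1,26.65,32.69,38.92,40.17,48.16,54.42,63.01,69.03,72.65,78.92,82.09,84.77,87.12,88.66,29.38,33.13,37.84,43.44,46.3,64.86,68.55,72.33,76.08,82.63,54.85,55.05,56.64,55.87,49.52,48.96,54.95,58.77,64.92,44.81,41.77,32.68,31.6,33.17,38.53,80.5,77.39,71.52,68.13,70.68,78.65,67.73,68.61,63.03,55.01,48,42.76,40.11,43.79,49.43,54.55,64.35,68.97,61.7,62.15,53.94,49.59,46.1,50.91,55.32,63.62,50.82,58.81,67.52,73.04,78.93,82.04,86.55,90.28,91.34,89.33,89.73,84.03,81.26,72.19,65.74,59.21,52.4,32.05,30.45,31.5,29.9,32.63,32.19,33.42,30.21,31.22,33.74,40.98,45.47,51.16,55.08,56.83,59.38,61.78,59.71,58.82,42.37,38.86,39.4,42.23,42.05,41.55,40.51,37.68,37.28,40.03,42.92,43.78,73.95,69.95,66.93,66.53,67.42,68.97,74.27,77.34,80.81,82.57,79.71,77.38,74.1,70.15,71.33,71.62,75.77,76.31,75.84,76.95
8,24.98,25.13,26.85,29.05,32.71,39.52,44.48,49.32,55.57,63.77,67.63,75.55,79.96,85.32,86.45,89.64,90.11,29.91,36.69,39.22,43.79,48.12,65.68,70.77,75.38,79.01,86.9,57.73,58.23,56.85,56.56,50.02,50.55,56.25,60.35,64.26,44.22,42.72,36.33,31.2,36.32,42.3,80.73,77.96,71.45,68.67,73.14,78.2,71.19,68.8,63.57,58.69,49.96,42.68,42.71,45.11,49.74,56.31,66.18,69.86,66,62.6,56.12,48.81,46.62,50.01,55,62.86,50.18,57.99,67.96,75.19,77.82,84.7,88.81,91.05,92.01,89.28,87.3,84.01,81.12,73.39,67.68,60.1,52.67,32.34,29.54,30.05,29.92,31.51,33.06,33.25,28.69,30.73,31.63,40.59,44.02,51.25,55.18,59.97,60.72,62.36,58.37,59.67,41.55,40.63,38.13,39.87,42.68,41.53,39.89,37.52,38.59,38.87,44.01,42.86,74.92,70.97,67.22,67.27,67.87,70.63,75.88,77.92,81.21,82.79,78.99,77.12,71.68,70.48,70.32,69.23,75.23,74.75,78.28,76.77
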